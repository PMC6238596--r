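site_fixture <- function(n = 6) {
  data.frame(peptide_id = sprintf("p%d", seq_len(n)),
             accession = sprintf("P%d", rep(1:3, length.out = n)),
             residue = "S", position = seq_len(n),
             stringsAsFactors = FALSE)
}

test_that("site-level group assignment wins over protein-level", {
  sites <- site_fixture()
  empty <- assign_groups(sites, NULL)
  expect_true(all(empty$group == "unclassified"))
  table <- data.frame(
    key = c("P1", site_key("P1", "S", 1)),
    level = c("protein", "site"),
    group = c("RNA binding", "MAPK"),
    color = c("#111111", "#222222"),
    stringsAsFactors = FALSE)
  out <- assign_groups(sites, table)
  expect_equal(out$group[out$accession == "P1" & out$position == 1], "MAPK")
  expect_equal(out$group[out$accession == "P1" & out$position == 4],
               "RNA binding")
  expect_equal(out$group[out$accession == "P2"][1], "unclassified")
  conflicting <- rbind(table, data.frame(key = "P1", level = "protein",
                                         group = "other", color = NA))
  expect_error(assign_groups(sites, conflicting), "conflicting")
})

test_that("outlier selection is strict on the cutoff", {
  d <- data.frame(site_key = c("a", "b"), differential = c(-1.0, 1.0),
                  stringsAsFactors = FALSE)
  expect_equal(nrow(select_outliers(d)$outliers), 0)
  d2 <- data.frame(site_key = c("a", "b", "c"),
                   differential = c(-1.2, 0, 2), stringsAsFactors = FALSE)
  out <- select_outliers(d2)
  expect_equal(out$outliers$site_key, c("a", "c"))
  expect_equal(out$outliers$direction, c("down", "up"))
  expect_equal(out$inside_fraction, 1 / 3)
  expect_error(select_outliers(d2, field = "nope"), "unknown contrast")
})

test_that("KS statistic matches hand-enumerated ECDF values", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # pooled points 0, 0.5, 1, 1.5: |F_x - F_y| = .5, 0, .5, 0
  expect_equal(ks_two_sample(c(0, 1), c(0.5, 1.5))$D, 0.5)
  # disjoint supports
  expect_equal(ks_two_sample(c(1, 2), c(5, 6, 7))$D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("asymptotic p agrees with the standard two-sample KS test", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(sample(10:60, 1))
    y <- rnorm(sample(10:60, 1), mean = runif(1, -1, 1))
    mine <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(mine$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-4)
  }
})

test_that("permutation p equals exhaustive enumeration for small samples", {
  set.seed(9)
  cases <- list(list(3, 3), list(4, 3), list(5, 4), list(5, 5))
  for (case in cases) {
    x <- rnorm(case[[1]])
    y <- rnorm(case[[2]], mean = 1)
    exact <- exhaustive_ks_p(x, y)
    n_perm <- 4000
    perm <- ks_two_sample(x, y, mode = "permutation", n_perm = n_perm,
                          seed = 99)$p_value
    tol <- 3 * sqrt(exact * (1 - exact) / n_perm) + 2 / n_perm
    expect_lt(abs(perm - exact), max(tol, 0.02))
  }
  expect_warning(ks_two_sample(rnorm(4), rnorm(4), mode = "permutation",
                               n_perm = 50), "n_perm")
})

test_that("group scan gates small groups, adjusts with BH and sorts by p", {
  set.seed(21)
  n <- 240
  groups <- rep(c("big_null", "shifted", "tiny", "unclassified"),
                c(80, 60, 3, 97))
  value <- rnorm(n)
  value[groups == "shifted"] <- value[groups == "shifted"] + 2
  d <- data.frame(site_key = sprintf("s%03d", 1:n), differential = value,
                  stringsAsFactors = FALSE)
  grouped <- data.frame(site_key = d$site_key, group = groups,
                        stringsAsFactors = FALSE)
  expect_message(res <- group_ks_scan(d, grouped), "skipped 1 group")
  expect_false("tiny" %in% res$group)
  expect_false("unclassified" %in% res$group)
  expect_equal(res$group[1], "shifted")
  expect_lt(res$q_value[1], 0.05)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_true(all(diff(res$p_value) >= 0))
  # q is non-decreasing in p-rank
  expect_true(all(diff(res$q_value) >= -1e-12))
  expect_true(all(res$D >= 0 & res$D <= 1))
})

test_that("kinase scan ranks the perturbed kinase's substrates", {
  set.seed(31)
  n <- 200
  d <- data.frame(site_key = sprintf("s%03d", 1:n),
                  differential = rnorm(n), stringsAsFactors = FALSE)
  pairs <- data.frame(
    kinase = rep(c("MTOR", "CDK1"), each = 20),
    ms_key = d$site_key[1:40],
    stringsAsFactors = FALSE)
  d$differential[1:20] <- d$differential[1:20] - 1.5
  res <- kinase_ks_scan(d, pairs)
  expect_equal(res$kinase[1], "MTOR")
  expect_lt(res$q_value[1], 0.05)
  expect_warning(empty <- kinase_ks_scan(d, pairs[0, ]), "no kinase")
  expect_equal(nrow(empty), 0)
})

test_that("hypergeometric p matches the closed-form small case", {
  background <- sprintf("g%02d", 1:10)
  foreground <- background[1:4]
  terms <- list(hit_term = background[1:5], void = character(0))
  res <- hypergeometric_enrichment(foreground, background, terms)
  # all 4 draws inside a term of 5 out of 10: C(5,4)C(5,0)/C(10,4) = 5/210
  expect_equal(nrow(res), 1)  # empty-background term skipped
  expect_equal(res$k, 4)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  # foreground == background makes enrichment impossible
  res2 <- hypergeometric_enrichment(background, background, terms["hit_term"])
  expect_equal(res2$p_value, 1)
  expect_error(hypergeometric_enrichment(c("zz", background[1]), background,
                                         terms), "not contained")
})

test_that("swapping a term's annotation maps upper tail to lower tail", {
  # independent check via choose() arithmetic on a small universe
  N <- 12; K <- 5; n <- 6
  upper <- function(k, K) {
    if (k > min(K, n)) return(0)
    sum(vapply(k:min(K, n), function(i) {
      choose(K, i) * choose(N - K, n - i) / choose(N, n)
    }, numeric(1)))
  }
  background <- sprintf("g%02d", 1:N)
  term <- background[1:K]
  set.seed(2)
  foreground <- sample(background, n)
  k <- length(intersect(foreground, term))
  res <- hypergeometric_enrichment(foreground, background,
                                   list(t = term, t_comp = setdiff(background,
                                                                   term)))
  expect_equal(res$p_value[res$term == "t"], upper(k, K), tolerance = 1e-12)
  # P(X_term >= k) == P(X_complement <= n - k): the swapped term's upper
  # tail at its own count complements the original strict upper tail
  p_comp <- res$p_value[res$term == "t_comp"]
  expect_equal(p_comp, 1 - upper(k + 1, K), tolerance = 1e-12)
})
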