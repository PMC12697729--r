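test_that("worst-rank quality reproduces the hand-computed 3x2 example", {
  tab <- metric_table(
    data.frame(id = c("d1", "d2", "d3"), m1 = c(1, 2, 3), m2 = c(3, 1, 2)),
    higher_better = c(FALSE, FALSE))
  q <- worst_rank_quality(tab)
  expect_equal(unname(q), c(3, 2, 3))
  expect_equal(names(which.min(q)), "d2")
})

test_that("quality is rank-based: single metric, dominance, monotone transforms", {
  tab <- make_metric_table(7, 1, seed = 2)
  q <- worst_rank_quality(tab)
  expect_equal(order(q), order(tab$metric_01))
  dom <- make_metric_table(9, 4, seed = 3, dominant_design = 4)
  expect_equal(which.min(worst_rank_quality(dom)), c(design_004 = 4L))
  # strictly monotone transform of one column leaves q unchanged
  tab2 <- dom
  tab2$metric_02 <- exp(tab2$metric_02)
  tab2 <- metric_table(as.data.frame(tab2)[, ], attr(dom, "higher_better"),
                       attr(dom, "weights"))
  expect_equal(worst_rank_quality(tab2), worst_rank_quality(dom))
  # weighted ranks enter before the max; missing values are named
  wtab <- metric_table(data.frame(id = c("a", "b"), m1 = c(1, 2), m2 = c(2, 1)),
                       higher_better = c(FALSE, FALSE), weights = c(10, 1))
  expect_equal(unname(worst_rank_quality(wtab)), c(10, 20))
  expect_error(metric_table(data.frame(id = "a", m1 = NA_real_), FALSE),
               "missing value.*m1")
})

test_that("TM-score is 1 for identical or rotated structures and symmetric", {
  h <- make_ideal_helix(30)
  expect_equal(tm_score(h, h), 1, tolerance = 1e-9)
  expect_equal(tm_score(h, helper_rotate(h, seed = 2)), 1, tolerance = 1e-6)
  p <- perturb_structure(h, 0.5, seed = 4)
  expect_equal(tm_score(h, p), tm_score(p, h), tolerance = 1e-6)
  expect_error(tm_score(helper_strand(2), h), "at least 3")
})

test_that("a helix and an extended strand of equal length score below 0.5", {
  n <- 30
  h <- make_ideal_helix(n)
  s <- helper_strand(n)
  impl <- tm_score(h, s)
  expect_lt(impl, 0.5)
  # independent oracle: direct numeric optimisation over superpositions
  xa <- coords(h, h$atoms$atom_name == "CA")
  xb <- coords(s)
  d0 <- max(0.5, 1.24 * (n - 15)^(1 / 3) - 1.8)
  tmsc <- function(par) {
    q <- par[1:4]; q <- q / sqrt(sum(q^2))
    m <- sweep(xa %*% binderkit:::quat_to_rot(q), 2, par[5:7], "+")
    -sum(1 / (1 + rowSums((m - xb)^2) / d0^2)) / n
  }
  set.seed(11)
  oracle <- -min(replicate(40, {
    start <- c(rnorm(4), colMeans(xb) - colMeans(xa) + rnorm(3))
    stats::optim(start, tmsc, method = "Nelder-Mead",
                 control = list(maxit = 400))$value
  }))
  expect_lt(oracle, 0.5)
  expect_gte(impl, oracle - 0.05)
})

test_that("sequence similarity is alignment identity over the longer length", {
  expect_equal(seq_sim("ACDE", "ACDE"), 1)
  expect_equal(seq_sim("ACDE", "ACDEFG"), 4 / 6)
  expect_equal(seq_sim("AAAA", "CCCC"), 0)
  expect_equal(seq_sim("KLMNP", "QRST"), 0)
  expect_equal(seq_sim("ACDEFG", "ACDE"), 4 / 6)  # symmetric
  expect_error(seq_sim("", "ACDE"), "empty sequence")
})

test_that("diversity combines structure and sequence similarity maxima", {
  h <- make_ideal_helix(20)
  x <- list(structure = h, sequence = strrep("A", 20))
  expect_equal(diversity(x, list()), 1)
  expect_equal(diversity(x, list(x)), 0)
  rot <- list(structure = helper_rotate(h, seed = 6), sequence = strrep("K", 20))
  expect_equal(diversity(x, list(rot), similarity_weights(1, 0)), 0,
               tolerance = 1e-6)
  expect_equal(diversity(x, list(rot), similarity_weights(0, 1)), 1)
  expect_error(similarity_weights(0.7, 0.5), "sum to 1")
})

test_that("greedy selection matches brute force on a 5-design fixture", {
  set.seed(21)
  helices <- lapply(c(12, 14, 16, 18, 20), make_ideal_helix)
  seqs <- c("AAAAKKKKLLLL", "AAAAKKKKLLLDDD", "MNPQRSTVWYMNPQRS",
            "AAAAKKKKLLLAAAKKKK", "GGGGGSSSSSGGGGGSSSSS")
  cands <- lapply(1:5, function(i) list(structure = helices[[i]], sequence = seqs[i]))
  names(cands) <- sprintf("d%d", 1:5)
  q <- c(d1 = 3, d2 = 1, d3 = 2, d4 = 5, d5 = 4)
  w <- similarity_weights()
  gamma <- 0.7
  sel <- qd_select(cands, q, k = 2, weights = w, gamma = gamma)

  # brute force the same greedy-consistent objective
  qn <- (q - min(q)) / diff(range(q))
  score1 <- -qn + gamma * 1
  first <- names(which.max(score1))
  score2 <- vapply(setdiff(names(q), first), function(id)
    -qn[[id]] + gamma * diversity(cands[[id]], cands[first], w), numeric(1))
  second <- names(which.max(score2))
  expect_equal(sel$id, c(first, second))
})

test_that("duplicates are not both selected when diversity matters", {
  h <- make_ideal_helix(15)
  dup <- list(structure = h, sequence = strrep("A", 15))
  distinct <- list(structure = helper_strand(15), sequence = strrep("W", 15))
  cands <- list(d1 = dup, d2 = dup, d3 = distinct)
  q <- c(d1 = 1, d2 = 1.2, d3 = 3)
  sel <- qd_select(cands, q, k = 2, gamma = 1)
  expect_setequal(sel$id, c("d1", "d3"))
  # gamma = 0 reduces to top-k by quality
  sel0 <- qd_select(cands, q, k = 2, gamma = 0)
  expect_equal(sel0$id, c("d1", "d2"))
  # k >= n returns everything
  expect_equal(nrow(qd_select(cands, q, k = 10, gamma = 0.5)), 3L)
})

test_that("Vendi score matches its eigen-decomposition closed forms", {
  expect_equal(vendi_score(kernel = matrix(1, 6, 6)), 1, tolerance = 1e-9)
  expect_equal(vendi_score(kernel = diag(5)), 5, tolerance = 1e-9)
  # permutation invariance and [1, n] bounds on random PSD kernels
  set.seed(31)
  for (i in 1:5) {
    A <- matrix(rnorm(25), 5, 5)
    K <- A %*% t(A)
    K <- K / sqrt(diag(K) %o% diag(K))   # unit diagonal
    v <- vendi_score(kernel = K)
    expect_gte(v, 1 - 1e-9)
    expect_lte(v, 5 + 1e-9)
    p <- sample(5)
    expect_equal(vendi_score(kernel = K[p, p]), v, tolerance = 1e-9)
    # independent check: direct entropy of the spectrum
    lam <- eigen(K / 5, only.values = TRUE)$values
    lam <- lam[lam > 1e-12]
    expect_equal(v, exp(-sum(lam * log(lam))), tolerance = 1e-8)
  }
  expect_error(vendi_score(kernel = matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
  # kernel-function form with a TM-score kernel on tiny structures
  items <- list(make_ideal_helix(12), helper_rotate(make_ideal_helix(12), 2),
                helper_strand(12))
  v <- vendi_score(items, kernel = function(x, y) tm_score(x, y))
  expect_gt(v, 1.5)   # two identical folds + one distinct
  expect_lt(v, 3)
})

test_that("the refold filter uses a strict 2.5 A boundary", {
  ids <- c("a", "b", "c", "d")
  expect_equal(refold_filter(ids, c(1.0, 2.4, 2.5, 3.0)), c("a", "b"))
  expect_equal(refold_filter(ids, rep(0, 4)), ids)
  expect_equal(refold_filter(character(0), numeric(0)), character(0))
  expect_error(refold_filter(ids, c(1, NA, 2, 3)), "missing RMSD.*b")
})
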