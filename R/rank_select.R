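# Quality ranking and quality-diversity selection: worst-rank aggregation,
# TM-score and sequence-identity similarity, greedy selection balancing
# quality against diversity, Vendi-score diversity, refold filter.

#' Metric table for design ranking
#'
#' A designs-by-metrics table with per-metric orientation (is higher better)
#' and positive rank weights.
#'
#' @param df data.frame whose first column `id` holds design identifiers and
#'   whose remaining columns are numeric metrics.
#' @param higher_better logical vector, one entry per metric column.
#' @param weights positive numeric vector, one entry per metric column
#'   (default all 1).
#' @return data.frame of class `bk_metric_table` with `higher_better` and
#'   `weights` attributes.
#' @export
metric_table <- function(df, higher_better, weights = NULL) {
  if (!"id" %in% names(df)) stop("metric table needs an 'id' column")
  mcols <- setdiff(names(df), "id")
  if (!length(mcols)) stop("metric table needs at least one metric column")
  if (anyDuplicated(df$id)) stop("design ids must be unique")
  for (m in mcols) {
    if (!is.numeric(df[[m]])) stop("metric column is not numeric: ", m)
    if (anyNA(df[[m]])) {
      i <- which(is.na(df[[m]]))[1]
      stop(sprintf("missing value in metric '%s' for design '%s'", m, df$id[i]))
    }
  }
  if (length(higher_better) != length(mcols))
    stop("higher_better must have one entry per metric")
  if (is.null(weights)) weights <- rep(1, length(mcols))
  if (length(weights) != length(mcols) || any(weights <= 0))
    stop("weights must be positive, one per metric")
  attr(df, "higher_better") <- stats::setNames(higher_better, mcols)
  attr(df, "weights") <- stats::setNames(weights, mcols)
  class(df) <- c("bk_metric_table", "data.frame")
  df
}

#' Read a metric table from CSV with a YAML sidecar
#'
#' The CSV has a header row with an `id` column; the sidecar (optional)
#' holds entries `metrics: {name: {higher_better: yes, weight: 2}}` for any
#' column that deviates from the default (lower is better, weight 1).
#'
#' @param csv path to the CSV file.
#' @param sidecar optional path to the YAML sidecar.
#' @return a [metric_table()].
#' @export
read_metric_table <- function(csv, sidecar = NULL) {
  df <- utils::read.csv(csv, stringsAsFactors = FALSE)
  mcols <- setdiff(names(df), "id")
  hb <- stats::setNames(rep(FALSE, length(mcols)), mcols)
  w <- stats::setNames(rep(1, length(mcols)), mcols)
  if (!is.null(sidecar)) {
    side <- yaml::read_yaml(sidecar)
    for (m in names(side$metrics %||% list())) {
      if (!m %in% mcols) stop("sidecar references unknown metric: ", m)
      e <- side$metrics[[m]]
      if (!is.null(e$higher_better)) hb[m] <- isTRUE(e$higher_better)
      if (!is.null(e$weight)) w[m] <- e$weight
    }
  }
  metric_table(df, hb, w)
}

#' Worst-rank quality score
#'
#' Ranks the designs within every metric (best value gets rank 1, ties get
#' the average rank, orientation respected), multiplies each rank by the
#' metric's weight, and aggregates per design by taking the worst (largest)
#' weighted rank. Lower q is better: the score rewards the best worst-case
#' performance across all metrics, and is invariant under strictly monotone
#' transforms of any metric column.
#'
#' @param table a [metric_table()].
#' @return named numeric vector q (names = design ids).
#' @examples
#' tab <- make_metric_table(5, 3, seed = 1)
#' worst_rank_quality(tab)
#' @export
worst_rank_quality <- function(table) {
  if (!inherits(table, "bk_metric_table")) stop("expected a metric_table()")
  hb <- attr(table, "higher_better")
  w <- attr(table, "weights")
  mcols <- names(hb)
  ranks <- vapply(mcols, function(m) {
    v <- table[[m]]
    r <- rank(if (hb[[m]]) -v else v, ties.method = "average")
    w[[m]] * r
  }, numeric(nrow(table)))
  ranks <- matrix(ranks, nrow = nrow(table))
  stats::setNames(apply(ranks, 1, max), table$id)
}

#' TM-score between two protein chains
#'
#' Length-normalised structural similarity in (0, 1] with
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8` (floored at 0.5), maximised over
#' rigid superpositions of the residue correspondence by fragment-seeded
#' iterative refinement. For equal-length chains the correspondence is
#' sequential; otherwise it is taken from the global sequence alignment of
#' [seq_sim()]. The score is normalised by the length of `b` (the
#' reference).
#'
#' @param a,b [bk_structure()]s with CA atoms (first protein chain used).
#' @return TM-score in (0, 1].
#' @examples
#' h <- make_ideal_helix(20)
#' tm_score(h, perturb_structure(h, 0.1)) > 0.9
#' @export
tm_score <- function(a, b) {
  xa <- ca_trace(a); xb <- ca_trace(b)
  if (nrow(xa) < 3 || nrow(xb) < 3) stop("tm_score: chains need at least 3 CA atoms")
  if (nrow(xa) == nrow(xb)) {
    pairs <- cbind(seq_len(nrow(xa)), seq_len(nrow(xb)))
  } else {
    pairs <- alignment_pairs(chain_sequence(a), chain_sequence(b))
    if (nrow(pairs) < 3) return(0)
  }
  Lref <- nrow(xb)
  d0 <- if (Lref > 15) max(0.5, 1.24 * (Lref - 15)^(1 / 3) - 1.8) else 0.5
  pa <- xa[pairs[, 1], , drop = FALSE]
  pb <- xb[pairs[, 2], , drop = FALSE]
  n <- nrow(pa)

  score_of <- function(mobile_aligned) {
    d2 <- rowSums((mobile_aligned - pb)^2)
    sum(1 / (1 + d2 / d0^2)) / Lref
  }
  refine <- function(sel) {
    best <- 0
    for (iter in 1:20) {
      if (length(sel) < 3) break
      fit <- rigid_align(pa, pb, weights = as.numeric(seq_len(n) %in% sel))
      d <- sqrt(rowSums((fit$coords - pb)^2))
      best <- max(best, score_of(fit$coords))
      new_sel <- which(d < max(d0, 1.0))
      if (length(new_sel) < 3) new_sel <- order(d)[1:3]
      if (identical(new_sel, sel)) break
      sel <- new_sel
    }
    best
  }
  best <- 0
  frag <- n
  while (frag >= 4) {
    step <- max(1L, n %/% 20L)
    for (start in seq(1, n - frag + 1, by = step))
      best <- max(best, refine(start:(start + frag - 1)))
    frag <- frag %/% 2
  }
  best <- max(best, refine(seq_len(n)))
  min(best, 1)
}

ca_trace <- function(structure) {
  a <- structure$atoms
  pc <- structure$chains$polymer_class
  chain <- structure$chains$chain_id[pc == "protein"][1]
  if (is.na(chain)) stop("no protein chain")
  a <- a[a$chain == chain & a$atom_name == "CA" & !a$is_virtual, ]
  a <- a[order(a$res_index), ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Sequence similarity by global alignment
#'
#' Identity count of the optimal global alignment (match 1, mismatch 0,
#' no gap penalty) divided by the length of the longer sequence.
#'
#' @param a,b amino-acid strings (one-letter).
#' @return similarity in `[0, 1]`.
#' @examples
#' seq_sim("ACDE", "ACDEFG")  # 4/6
#' @export
seq_sim <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("seq_sim: empty sequence")
  matches <- global_alignment_matches(a, b)
  matches / max(nchar(a), nchar(b))
}

identity_submat <- function(chars) {
  m <- diag(1, length(chars))
  dimnames(m) <- list(chars, chars)
  m
}

global_alignment_matches <- function(a, b) {
  chars <- sort(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    substitutionMatrix = identity_submat(chars),
    gapOpening = 0, gapExtension = 0, type = "global", scoreOnly = FALSE
  )
  # with this scoring the alignment score is exactly the identity count
  as.numeric(Biostrings::score(al))
}

alignment_pairs <- function(a, b) {
  chars <- sort(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    substitutionMatrix = identity_submat(chars),
    gapOpening = 0, gapExtension = 0, type = "global"
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  i <- 0L; j <- 0L
  out <- matrix(0L, 0, 2)
  for (k in seq_along(pat)) {
    if (pat[k] != "-") i <- i + 1L
    if (sub[k] != "-") j <- j + 1L
    if (pat[k] != "-" && sub[k] != "-") out <- rbind(out, c(i, j))
  }
  out
}

#' Similarity weights for the diversity term
#' @param w_struct,w_seq non-negative weights summing to 1.
#' @export
similarity_weights <- function(w_struct = 0.5, w_seq = 0.5) {
  if (w_struct < 0 || w_seq < 0 || abs(w_struct + w_seq - 1) > 1e-9)
    stop("similarity weights must be non-negative and sum to 1")
  list(w_struct = w_struct, w_seq = w_seq)
}

#' Diversity of a design with respect to a candidate set
#'
#' `1 - (w_struct * max TM-score to the set + w_seq * max sequence identity
#' to the set)`; an empty set gives diversity 1 (both maxima are 0 by
#' convention).
#'
#' @param x a design: list with elements `structure` ([bk_structure()]) and
#'   `sequence` (string); either may be omitted if its weight is 0.
#' @param A list of designs of the same form (possibly empty).
#' @param weights a [similarity_weights()].
#' @return diversity in `[0, 1]`.
#' @export
diversity <- function(x, A, weights = similarity_weights()) {
  if (!length(A)) return(1)
  struct_sim <- if (weights$w_struct > 0)
    max(vapply(A, function(a) tm_score(x$structure, a$structure), numeric(1)))
  else 0
  sq_sim <- if (weights$w_seq > 0)
    max(vapply(A, function(a) seq_sim(x$sequence, a$sequence), numeric(1)))
  else 0
  1 - (weights$w_struct * struct_sim + weights$w_seq * sq_sim)
}

#' Greedy quality-diversity selection
#'
#' Starting from the empty set, repeatedly adds the design maximising
#' `-q_norm(x) + gamma * Diversity(x, S)` with respect to the already
#' selected set `S`, where `q_norm` is the worst-rank quality min-max
#' normalised to `[0, 1]`. Ties break on the lexicographically smaller
#' design id. With `gamma = 0` this reduces to the top-k by quality.
#'
#' @param candidates named list of designs (see [diversity()]); names are
#'   the design ids and must match `names(q)`.
#' @param q named quality scores from [worst_rank_quality()] (lower better).
#' @param k selection budget (>= 1).
#' @param weights a [similarity_weights()].
#' @param gamma diversity weight (>= 0).
#' @return data.frame with `id`, `q`, `diversity`, `score` in pick order.
#' @export
qd_select <- function(candidates, q, k, weights = similarity_weights(),
                      gamma = 0.5) {
  if (k < 1) stop("k must be >= 1")
  ids <- names(candidates)
  if (is.null(ids) || !setequal(ids, names(q)))
    stop("candidates and q must carry matching design ids")
  q <- q[ids]
  qn <- if (diff(range(q)) > 0) (q - min(q)) / diff(range(q)) else rep(0, length(q))
  names(qn) <- ids

  # pairwise similarities computed lazily against the selected set
  selected <- character(0)
  rows <- list()
  remaining <- ids
  while (length(selected) < k && length(remaining)) {
    div <- vapply(remaining, function(id)
      diversity(candidates[[id]], candidates[selected], weights), numeric(1))
    sc <- -qn[remaining] + gamma * div
    ord <- order(-sc, remaining)    # tie-break: smaller id
    pick <- remaining[ord[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      id = pick, q = unname(q[pick]), diversity = unname(div[pick]),
      score = unname(sc[pick]), stringsAsFactors = FALSE
    )
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  do.call(rbind, rows)
}

#' Vendi score: effective number of distinct items
#'
#' The exponential of the von Neumann entropy of the trace-normalised
#' similarity-kernel matrix. Equals 1 when all items are identical and n
#' when they are pairwise orthogonal.
#'
#' @param items list of items, or NULL when `kernel` is already a matrix.
#' @param kernel symmetric positive-semidefinite similarity function
#'   `(x, y)` with unit self-similarity, or a precomputed kernel matrix.
#' @return Vendi score in `[1, n]`.
#' @examples
#' vendi_score(kernel = diag(4))       # 4
#' vendi_score(kernel = matrix(1, 3, 3))  # 1
#' @export
vendi_score <- function(items = NULL, kernel) {
  K <- if (is.matrix(kernel)) kernel else {
    n <- length(items)
    m <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in i:n)
      m[i, j] <- m[j, i] <- if (i == j) 1 else kernel(items[[i]], items[[j]])
    m
  }
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("vendi_score: kernel matrix must be symmetric")
  lam <- eigen(K / sum(diag(K)), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  lam <- lam[lam > 0]
  exp(-sum(lam * log(lam)))
}

#' Refolding self-consistency filter
#'
#' Keeps designs whose refold RMSD is strictly below the threshold.
#'
#' @param designs character vector of design ids.
#' @param rmsd_values numeric RMSD per design (Angstrom), no missing values.
#' @param threshold RMSD threshold in Angstrom (default 2.5; strict `<`).
#' @return character vector of surviving design ids.
#' @export
refold_filter <- function(designs, rmsd_values, threshold = 2.5) {
  if (length(designs) != length(rmsd_values))
    stop("designs and rmsd_values must have equal length")
  if (anyNA(rmsd_values)) {
    stop("missing RMSD for design(s): ",
         paste(designs[is.na(rmsd_values)], collapse = ", "))
  }
  designs[rmsd_values < threshold]
}
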