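# Filtering/ranking pipeline: analyze designed complexes, merge externally
# produced metric columns, apply the refold filter, aggregate quality by
# worst rank, and run the greedy quality-diversity selection. The upstream
# generation, inverse-folding, refolding and affinity stages are external;
# their outputs enter as PDB files and metric columns.

#' Pipeline configuration
#'
#' One document holding every knob of the filtering/selection pipeline.
#' Unknown keys are rejected.
#'
#' @param k selection budget.
#' @param gamma diversity weight of the greedy selection.
#' @param w_struct,w_seq similarity weights (must sum to 1).
#' @param refold_threshold RMSD filter threshold in Angstrom.
#' @param refold_column name of the metric column holding refold RMSD
#'   (NULL disables the filter).
#' @param sasa_points sphere points per atom for surface metrics.
#' @param metric_weights optional named rank weights per metric column.
#' @param higher_better optional named orientation overrides.
#' @param seed RNG seed recorded in the report.
#' @return object of class `bk_pipeline_config`.
#' @export
pipeline_config <- function(k = 5, gamma = 0.5, w_struct = 0.5, w_seq = 0.5,
                            refold_threshold = 2.5, refold_column = "refold_rmsd",
                            sasa_points = 240, metric_weights = NULL,
                            higher_better = NULL, seed = 1) {
  cfg <- list(k = k, gamma = gamma, w_struct = w_struct, w_seq = w_seq,
              refold_threshold = refold_threshold,
              refold_column = refold_column, sasa_points = sasa_points,
              metric_weights = metric_weights, higher_better = higher_better,
              seed = seed)
  if (k < 1) stop("k must be >= 1")
  if (gamma < 0) stop("gamma must be >= 0")
  similarity_weights(w_struct, w_seq)  # validates
  structure(cfg, class = "bk_pipeline_config")
}

#' @rdname pipeline_config
#' @param file YAML file with `pipeline_config()` arguments as keys.
#' @export
pipeline_config_from_yaml <- function(file) {
  doc <- yaml::read_yaml(file)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, doc)
}

#' Run the filtering / ranking / selection pipeline
#'
#' Executes, in order: per-design interface analysis (hydrogen bonds, salt
#' bridges, buried surface area, hydrophobic patch, solubility), merge of
#' externally supplied metric columns, the refold-RMSD filter, worst-rank
#' quality aggregation, and greedy quality-diversity selection. The result
#' is a pure function of (inputs, config): reruns with the same inputs give
#' identical selections.
#'
#' @param designs named list of [bk_structure()] complexes (design chain
#'   `"A"`, remaining chains the target), or a directory of PDB files whose
#'   basenames become design ids.
#' @param metrics optional data.frame of external metric columns with an
#'   `id` column (e.g. confidence scores, refold RMSD).
#' @param config a [pipeline_config()].
#' @param analyze run the interface-analysis stage (set FALSE when all
#'   metrics are supplied externally).
#' @return list of class `bk_pipeline_result` with `selection` (data.frame
#'   in pick order), `table` (the merged [metric_table()]), `report`
#'   (per-design metric list), `survivors`, `config_hash` and `log`.
#' @export
run_pipeline <- function(designs, metrics = NULL, config = pipeline_config(),
                         analyze = TRUE) {
  log <- character(0)
  say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.character(designs) && length(designs) == 1L) {
    files <- sort(list.files(designs, pattern = "\\.pdb$", full.names = TRUE))
    if (!length(files)) stop("no PDB files in ", designs)
    designs <- stats::setNames(
      lapply(files, function(f) read_pdb(paste(readLines(f), collapse = "\n"))),
      sub("\\.pdb$", "", basename(files)))
  }
  ids <- names(designs)
  if (is.null(ids) || anyDuplicated(ids)) stop("designs must carry unique names")
  say("pipeline start: %d designs", length(ids))

  df <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (analyze) {
    rep_list <- stage("analyze", lapply(designs, function(s) {
      r <- interaction_report(s, design_chain = "A",
                              n_points = config$sasa_points)
      r[c("n_hbonds", "n_salt_bridges", "buried_sasa",
          "largest_hydrophobic_patch", "solubility_score")]
    }))
    an <- do.call(rbind, lapply(rep_list, as.data.frame))
    df <- cbind(df, an)
    say("analyze: %d metric columns", ncol(an))
  } else rep_list <- NULL

  if (!is.null(metrics)) {
    stage("merge", {
      if (!"id" %in% names(metrics)) stop("external metrics need an 'id' column")
      missing <- setdiff(ids, metrics$id)
      if (length(missing))
        stop("external metrics missing designs: ", paste(missing, collapse = ", "))
      df <- merge(df, metrics, by = "id", sort = FALSE)
      df <- df[match(ids, df$id), , drop = FALSE]
    })
    say("merged %d external metric columns", ncol(metrics) - 1L)
  }

  survivors <- ids
  if (!is.null(config$refold_column) && config$refold_column %in% names(df)) {
    survivors <- stage("refold_filter",
                       refold_filter(df$id, df[[config$refold_column]],
                                     config$refold_threshold))
    say("refold filter: %d/%d designs survive", length(survivors), length(ids))
    if (!length(survivors)) stop("pipeline stage 'refold_filter' failed: no design survives")
    df <- df[df$id %in% survivors, , drop = FALSE]
  }

  mcols <- setdiff(names(df), c("id", config$refold_column))
  hb_default <- c(n_hbonds = TRUE, n_salt_bridges = TRUE, buried_sasa = TRUE,
                  largest_hydrophobic_patch = FALSE, solubility_score = TRUE)
  hb <- stats::setNames(rep(FALSE, length(mcols)), mcols)
  known <- intersect(mcols, names(hb_default))
  hb[known] <- hb_default[known]
  if (!is.null(config$higher_better)) {
    ov <- intersect(names(config$higher_better), mcols)
    hb[ov] <- config$higher_better[ov]
  }
  w <- rep(1, length(mcols))
  if (!is.null(config$metric_weights)) {
    i <- match(names(config$metric_weights), mcols)
    w[i[!is.na(i)]] <- config$metric_weights[!is.na(i)]
  }
  tab <- stage("rank", metric_table(df[, c("id", mcols)], unname(hb), w))
  q <- worst_rank_quality(tab)
  say("worst-rank quality: best design %s (q = %.2f)",
      names(q)[which.min(q)], min(q))

  cands <- stage("select", lapply(df$id, function(id) list(
    structure = designs[[id]],
    sequence = chain_sequence(designs[[id]], "A"))))
  names(cands) <- df$id
  selection <- stage("select", qd_select(
    cands, q, k = config$k,
    weights = similarity_weights(config$w_struct, config$w_seq),
    gamma = config$gamma))
  say("selected %d designs", nrow(selection))

  structure(list(selection = selection, table = tab, report = rep_list,
                 survivors = survivors,
                 config_hash = config_hash(config), log = log),
            class = "bk_pipeline_result")
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  # small stable polynomial checksum; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.bk_pipeline_result <- function(x, ...) {
  cat("bk_pipeline_result (config ", x$config_hash, ")\n", sep = "")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  print(x$selection)
  invisible(x)
}
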