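## End-to-end screening funnel.
##
## Stage order: docking-score top fraction -> classifier probability
## filter -> affinity gate -> diversity clustering with medoid
## representatives -> dose-response simulation -> novelty annotation ->
## ranking by (probability, potency). Every molecule's terminal stage is
## recorded so the funnel is auditable, and all stochastic steps are
## seeded so a rerun with the same config reproduces the report
## bit-exactly.

PIPELINE_STAGES <- c("scored", "top_fraction", "prob_pass", "affinity_pass",
                     "clustered", "simulated")

#' Pipeline configuration
#'
#' @param top_fraction fraction of best-scored molecules retained
#'   (default 0.01, the top 1 percent).
#' @param probability_threshold antagonist-probability cutoff
#'   (default 0.84, boundary inclusive).
#' @param min_pKd affinity cutoff (default 5.5, boundary inclusive).
#' @param novelty_threshold maximum-Tanimoto novelty cutoff (default 0.4).
#' @param k_range candidate cluster counts (`NULL`: `2 .. min(n - 1, 10)`).
#' @param seed master seed for all stochastic steps.
#' @param linkage clustering linkage.
#' @param cascade [cascade_parameters()] for the simulations.
#' @param grid [dose_grid()] for the simulations.
#' @param simulate_mode `"antagonist"` (default) or `"agonist"`.
#' @param sim_t_end,sim_n_steps simulation window and output steps.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(top_fraction = 0.01, probability_threshold = 0.84,
                            min_pKd = 5.5, novelty_threshold = 0.4,
                            k_range = NULL, seed = 1L, linkage = "average",
                            cascade = cascade_parameters(), grid = dose_grid(),
                            simulate_mode = "antagonist",
                            sim_t_end = 300, sim_n_steps = 500L) {
  if (top_fraction <= 0 || top_fraction > 1) stop_fmt("top_fraction must lie in (0, 1]")
  for (v in c(probability_threshold, novelty_threshold))
    if (v < 0 || v > 1.01) stop_fmt("thresholds on probabilities must lie in [0, 1]")
  structure(list(top_fraction = top_fraction,
                 probability_threshold = probability_threshold,
                 min_pKd = min_pKd, novelty_threshold = novelty_threshold,
                 k_range = k_range, seed = seed, linkage = linkage,
                 cascade = cascade, grid = grid,
                 simulate_mode = simulate_mode,
                 sim_t_end = sim_t_end, sim_n_steps = sim_n_steps),
            class = "pipeline_config")
}

#' Retain the top-scoring fraction of molecules
#'
#' Keeps `ceiling(fraction * n)` molecules with the most negative best
#' docking scores; ties at the cut are broken by molecule id.
#'
#' @param molecules data.frame with `id` and `best_score` columns.
#' @param fraction fraction to retain (default 0.01).
#' @return the retained rows in score order.
#' @export
select_top_fraction <- function(molecules, fraction = 0.01) {
  if (!nrow(molecules)) stop_fmt("empty molecule set")
  stopifnot(all(c("id", "best_score") %in% names(molecules)))
  m <- ceiling(fraction * nrow(molecules))
  ord <- order(molecules$best_score, molecules$id)
  molecules[ord[seq_len(m)], , drop = FALSE]
}

#' Run the screening funnel
#'
#' @param molecules data.frame: `id`, `best_score` (minimum docking score
#'   over poses), `pKd`; optionally `smiles`.
#' @param pose_features feature matrix for all poses (e.g. from
#'   [build_feature_matrix()]) with attribute `molecule_id`, or a list
#'   `list(features, molecule_id)`.
#' @param model a trained [train_rf()] classifier.
#' @param config a [pipeline_config()].
#' @param fingerprints optional molecule-by-bit 0/1 matrix (rownames =
#'   molecule ids) for clustering/novelty; computed from `smiles` via
#'   [ecfp4()] when absent.
#' @param reference_fps optional reference fingerprint matrix (or list of
#'   `bitfp`) for novelty annotation.
#' @return list of class `pipeline_result`: `records` (one row per
#'   molecule: probability, pKd, cluster, representative flag, novelty,
#'   x50, amplitude, stage reached, rank), `funnel` (per-stage counts),
#'   `curves`, `manifest`, `status` (0, or 2 when a stage emptied the
#'   funnel).
#' @export
run_pipeline <- function(molecules, pose_features, model, config = pipeline_config(),
                         fingerprints = NULL, reference_fps = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.list(pose_features) && !is.matrix(pose_features)) {
    pf <- as.matrix(pose_features$features)
    pf_mol <- pose_features$molecule_id
  } else {
    pf <- as.matrix(pose_features)
    pf_mol <- attr(pose_features, "molecule_id")
  }
  if (is.null(pf_mol) || length(pf_mol) != nrow(pf))
    stop_fmt("pose_features must carry one molecule_id per row")
  stopifnot(all(c("id", "best_score", "pKd") %in% names(molecules)))

  rec <- data.frame(molecule_id = molecules$id,
                    best_score = molecules$best_score,
                    pKd = molecules$pKd,
                    probability = NA_real_, cluster = NA_integer_,
                    representative = FALSE, novelty_tc = NA_real_,
                    x50_uM = NA_real_, amplitude_uM = NA_real_,
                    stage = "scored", rank = NA_integer_,
                    stringsAsFactors = FALSE)
  rownames(rec) <- rec$molecule_id
  status <- 0L
  counts <- setNames(integer(length(PIPELINE_STAGES)), PIPELINE_STAGES)
  counts["scored"] <- nrow(rec)
  curves <- list()

  bail <- function(stage) {
    warn_fmt("stage '%s' emptied the candidate funnel", stage)
    status <<- 2L
  }

  # stage 1: top fraction by docking score
  top <- select_top_fraction(molecules, config$top_fraction)
  rec[top$id, "stage"] <- "top_fraction"
  counts["top_fraction"] <- nrow(top)
  alive <- top$id

  # stage 2: classifier probability filter
  if (length(alive)) {
    for (id in alive) {
      rows <- which(pf_mol == id)
      if (!length(rows)) stop_fmt("no pose features for molecule '%s'", id)
      rec[id, "probability"] <- predict_molecule_probability(
        model, pf[rows, , drop = FALSE], class = "antagonist")
    }
    alive <- alive[rec[alive, "probability"] >= config$probability_threshold]
    if (!length(alive)) bail("prob_pass")
    rec[alive, "stage"] <- "prob_pass"
    counts["prob_pass"] <- length(alive)
  }

  # stage 3: affinity gate
  if (length(alive)) {
    gated <- suppressWarnings(
      affinity_gate(data.frame(id = alive, pKd = rec[alive, "pKd"]),
                    min_pKd = config$min_pKd))
    alive <- gated$id
    if (!length(alive)) bail("affinity_pass")
    rec[alive, "stage"] <- "affinity_pass"
    counts["affinity_pass"] <- length(alive)
  }

  # stage 4: diversity clustering + medoid representatives
  fps_alive <- NULL
  if (length(alive)) {
    if (is.null(fingerprints)) {
      if (is.null(molecules$smiles))
        stop_fmt("need either 'fingerprints' or a 'smiles' column for clustering")
      fp_list <- lapply(alive, function(id)
        ecfp4(molecules$smiles[molecules$id == id], molecule_id = id))
      fps_alive <- do.call(rbind, lapply(fp_list, as.numeric))
      rownames(fps_alive) <- alive
    } else {
      missing <- setdiff(alive, rownames(fingerprints))
      if (length(missing)) stop_fmt("no fingerprint for: %s", paste(missing, collapse = ", "))
      fps_alive <- fingerprints[alive, , drop = FALSE]
    }
    if (length(alive) >= 4) {
      D <- tanimoto_distance_matrix(fps_alive)
      k_range <- config$k_range %||% seq(2L, min(length(alive) - 1L, 10L))
      k_range <- k_range[k_range >= 2 & k_range <= length(alive) - 1]
      assign <- select_k_by_silhouette(D, k_range, linkage = config$linkage)
      rec[alive, "cluster"] <- assign$labels
      reps <- assign$representatives
    } else {
      rec[alive, "cluster"] <- seq_along(alive)
      reps <- alive
    }
    rec[reps, "representative"] <- TRUE
    rec[alive, "stage"] <- "clustered"
    counts["clustered"] <- length(alive)

    # stage 5: dose-response simulation for representatives
    for (id in reps) {
      curve <- dose_response(config$cascade, affinity(rec[id, "pKd"]),
                             grid = config$grid, mode = config$simulate_mode,
                             t_end = config$sim_t_end, n_steps = config$sim_n_steps)
      curves[[id]] <- curve
      if (!isTRUE(curve$hill$degenerate)) {
        rec[id, "x50_uM"] <- curve$hill$x50_uM
        rec[id, "amplitude_uM"] <- abs(curve$hill$top - curve$hill$bottom)
      }
      rec[id, "stage"] <- "simulated"
    }
    counts["simulated"] <- length(reps)

    # novelty annotation for the simulated candidates
    if (!is.null(reference_fps)) {
      for (id in reps) {
        nv <- novelty(structure(fps_alive[id, ] > 0, class = "bitfp",
                                molecule_id = id),
                      reference_fps, threshold = config$novelty_threshold)
        rec[id, "novelty_tc"] <- nv$max_tanimoto
      }
    }

    # final ranking: probability (desc), then potency (x50 asc)
    final <- rec$molecule_id[rec$stage == "simulated"]
    ord <- order(-rec[final, "probability"], rec[final, "x50_uM"], final)
    rec[final[ord], "rank"] <- seq_along(final)
  }

  rec$stage <- factor(rec$stage, levels = PIPELINE_STAGES)
  manifest <- list(
    config_hash = hash_ints(utf8ToInt(paste(deparse(unclass(config)), collapse = ""))),
    seed = config$seed,
    n_molecules = nrow(rec), n_poses = nrow(pf),
    stage_counts = counts,
    package_version = as.character(utils::packageVersion("a2ascreen")))
  structure(list(records = rec[order(rec$rank, na.last = TRUE), ],
                 funnel = counts, curves = curves, manifest = manifest,
                 status = status),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  funnel:",
      paste(sprintf("%s=%d", names(x$funnel), x$funnel), collapse = " -> "), "\n")
  fin <- x$records[!is.na(x$records$rank), , drop = FALSE]
  if (nrow(fin)) {
    cat("  final candidates:\n")
    print(fin[, c("molecule_id", "probability", "pKd", "x50_uM", "novelty_tc", "rank")],
          row.names = FALSE, digits = 4)
  } else cat("  no final candidates\n")
  invisible(x)
}

#' Render the screening report
#'
#' Writes a human-readable funnel summary plus the machine-readable
#' candidate table.
#'
#' @param result a `pipeline_result` (or its `records` data.frame).
#' @param dir output directory (`NULL`: nothing written).
#' @return invisibly, the summary text lines.
#' @export
render_report <- function(result, dir = NULL) {
  rec <- if (inherits(result, "pipeline_result")) result$records else result
  counts <- if (inherits(result, "pipeline_result")) result$funnel else {
    st <- factor(rec$stage, levels = PIPELINE_STAGES)
    rev(cumsum(rev(table(st))))
  }
  lines <- c("screening funnel:",
             sprintf("  %-14s %d", names(counts), counts),
             "", sprintf("final ranked candidates: %d", sum(!is.na(rec$rank))))
  fin <- rec[!is.na(rec$rank), , drop = FALSE]
  if (nrow(fin))
    lines <- c(lines, sprintf(
      "  #%d %s  p=%.3f pKd=%.2f x50=%.4g uM%s", fin$rank, fin$molecule_id,
      fin$probability, fin$pKd, fin$x50_uM,
      ifelse(is.na(fin$novelty_tc), "",
             sprintf(" maxTc=%.2f", fin$novelty_tc))))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(lines, file.path(dir, "report.txt"))
    write_results_table(rec, file.path(dir, "candidates.tsv"))
  }
  invisible(lines)
}
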