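#' Default analysis configuration
#'
#' All tunable parameters of the per-subject pipeline in one list: montage
#' and node sets, bands (the five standard bands plus the full 1-45 Hz
#' band), broadband pre-filter, epoch scheme, phase-trim, the zero-PLI
#' distance cap, clustering normalization and the community seed.
#'
#' @param epoch_length_s Epoch length in seconds (default 10; set 90 for a
#'   single epoch).
#' @param total_s Analyzed duration in seconds (default 90).
#' @return A `pligraph_config` list.
#' @export
default_config <- function(epoch_length_s = 10, total_s = 90) {
  bands <- rbind(eeg_bands(),
                 data.frame(name = "full", f_lo = 1, f_hi = 45))
  structure(list(
    montage = ifcn_montage(),
    node_sets = list(whole = ifcn_montage(),
                     frontotemporal = frontotemporal_set()),
    bands = bands,
    broadband = c(0.1, 45),
    fs = 500,
    epoch_length_s = epoch_length_s,
    total_s = total_s,
    trim_s = 0.5,
    eps = 1e-6,
    cc_normalization = "unit",
    community_seed = 1L,
    spectral_grid = 1:45
  ), class = "pligraph_config")
}

# Case-insensitive montage matching; extra channels dropped with a warning,
# missing montage channels are an error.
match_montage <- function(rec, montage) {
  idx <- match(tolower(montage), tolower(rec$labels))
  if (anyNA(idx)) {
    pg_stop(sprintf("recording is missing montage channel(s): %s",
                    paste(montage[is.na(idx)], collapse = ", ")),
            "pg_label_error")
  }
  extra <- setdiff(seq_along(rec$labels), idx)
  if (length(extra) > 0) {
    warning(sprintf("dropping %d non-montage channel(s): %s", length(extra),
                    paste(rec$labels[extra], collapse = ", ")))
  }
  rec$data <- rec$data[idx, , drop = FALSE]
  rec$labels <- montage
  rownames(rec$data) <- montage
  rec
}

#' Run the full per-subject pipeline
#'
#' Average reference, broadband and per-band filtering, epoching, PLI
#' connectivity, then weighted-network, MST and community metrics for the
#' whole 25-node network and the 16-node frontotemporal subnetwork in every
#' band, plus the spectral summary.
#'
#' @param rec An [eeg_recording()].
#' @param config A [default_config()] list.
#' @param keep_edges If TRUE, also return the long PLI edge table.
#' @return List of tidy data.frames: `spectral`, `network`, `mst`,
#'   `community` (and `edges` if requested), each carrying `subject_id`.
#'   The serialized configuration and package version are attached as
#'   `attr(, "provenance")`.
#' @export
run_subject <- function(rec, config = default_config(), keep_edges = FALSE) {
  rec <- match_montage(rec, config$montage)
  rec <- average_reference(rec)
  epochs <- make_epochs(rec, bands = config$bands,
                        epoch_length_s = config$epoch_length_s,
                        total_s = config$total_s,
                        broadband = config$broadband)
  cms <- pli_connectivity(epochs, trim_s = config$trim_s)
  sid <- rec$subject_id
  net <- list(); mst <- list(); com <- list(); edg <- list()
  for (bn in names(cms)) {
    for (ns in names(config$node_sets)) {
      g <- build_graph(cms[[bn]], node_set = config$node_sets[[ns]],
                       tag = ns, eps = config$eps)
      net[[paste(bn, ns)]] <- network_metrics(g, sid, config$cc_normalization)
      mst[[paste(bn, ns)]] <- mst_metrics(kruskal_mst(g), sid)
      com[[paste(bn, ns)]] <- community_metrics(g, config$community_seed, sid)
    }
    if (keep_edges) {
      e <- pli_edges(cms[[bn]])
      e$subject_id <- sid
      edg[[bn]] <- e
    }
  }
  out <- list(
    spectral = spectral_summary(rec, bands = config$bands,
                                grid = config$spectral_grid),
    network = do.call(rbind, unname(net)),
    mst = do.call(rbind, unname(mst)),
    community = do.call(rbind, unname(com))
  )
  if (keep_edges) out$edges <- do.call(rbind, unname(edg))
  attr(out, "provenance") <- list(
    package_version = as.character(utils::packageVersion("pligraph")),
    config = jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  )
  out
}

# Long metric tables -> one wide feature row per subject, columns named
# <node_set>_<band>_<metric>.
widen_features <- function(res) {
  long <- rbind(
    stats::reshape(res$network, direction = "long",
                   varying = c("mean_pli", "cc", "pl"),
                   v.names = "value", timevar = "metric",
                   times = c("mean_pli", "cc", "pl"))[,
                     c("subject_id", "band", "node_set", "metric", "value")],
    stats::reshape(res$mst, direction = "long",
                   varying = c("diameter", "diameter_norm", "leaf_number",
                               "leaf_fraction", "bc_max", "tree_hierarchy",
                               "kappa"),
                   v.names = "value", timevar = "metric",
                   times = c("diameter", "diameter_norm", "leaf_number",
                             "leaf_fraction", "bc_max", "tree_hierarchy",
                             "kappa"))[,
                     c("subject_id", "band", "node_set", "metric", "value")],
    stats::reshape(res$community, direction = "long",
                   varying = c("q", "n_modules", "mean_pc"),
                   v.names = "value", timevar = "metric",
                   times = c("q", "n_modules", "mean_pc"))[,
                     c("subject_id", "band", "node_set", "metric", "value")]
  )
  long$feature <- paste(long$node_set, long$band, long$metric, sep = "_")
  wide <- stats::reshape(long[, c("subject_id", "feature", "value")],
                         direction = "wide", idvar = "subject_id",
                         timevar = "feature")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Per-subject feature table for a cohort
#'
#' Runs [run_subject()] on every recording and joins the wide network
#' feature row with the clinical record.
#'
#' @param cohort List of `list(recording, record)` as from
#'   [simulate_cohort()].
#' @param config A [default_config()].
#' @return data.frame, one row per subject: clinical covariates plus one
#'   column per node_set x band x metric feature.
#' @export
cohort_features <- function(cohort, config = default_config()) {
  rows <- lapply(cohort, function(subj) {
    res <- run_subject(subj$recording, config)
    merge(subj$record, widen_features(res), by = "subject_id")
  })
  do.call(rbind, rows)
}

#' Run the cohort-level statistical stage
#'
#' Group comparisons (ANOVA + Tukey) of every network feature, Spearman
#' correlations of every feature with the severity score among patients,
#' and stepwise regression of severity on network and clinical candidates.
#'
#' @param features Subject x feature table from [cohort_features()].
#' @param candidates Candidate predictors for the stepwise model; default:
#'   the frontotemporal panel (mean PLI, CC, PL and MST diameter per band)
#'   plus age, age of onset, duration, ASM count and the history flags.
#'   Whole-network metrics are near-duplicates of the frontotemporal ones
#'   whenever the effect is frontotemporal (the whole-network value is a
#'   superset average), and stepwise selection among near-duplicates is
#'   arbitrary; pass an explicit vector to include them.
#' @param response Severity column (default "va2").
#' @return List: `group_tests` (one row per feature: F, p), `correlations`
#'   (one row per feature: Spearman r, p, n), `regression` (the
#'   [stepwise_regression()] result).
#' @export
cohort_stats <- function(features, candidates = NULL, response = "va2") {
  meta <- c("subject_id", "group", "age", "sex", "age_of_onset", "duration",
            "seizure_freq_class", "dre", "va2", "n_asm", "febrile_history",
            "family_history", "status_epilepticus", "coupling_strength")
  feat_cols <- setdiff(names(features), meta)
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  if (is.null(candidates)) {
    net_cand <- feat_cols[grepl("^frontotemporal_.*_(mean_pli|cc|pl|diameter)$",
                                feat_cols)]
    clin_cand <- intersect(c("age", "age_of_onset", "duration", "n_asm",
                             "febrile_history", "family_history",
                             "status_epilepticus"), names(features))
    candidates <- c(net_cand, clin_cand)
  }
  gt <- do.call(rbind, lapply(feat_cols, function(f) {
    res <- tryCatch(group_compare(features, f),
                    pligraph_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(feature = f, f_stat = res$f, p = res$p,
               stringsAsFactors = FALSE)
  }))
  cors <- do.call(rbind, lapply(feat_cols, function(f) {
    res <- tryCatch(severity_correlation(features, f, response),
                    pligraph_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(feature = f, r = res$r, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  }))
  # histories are logical; coerce for the design matrix
  reg_tab <- features
  for (v in candidates) {
    if (is.logical(reg_tab[[v]])) reg_tab[[v]] <- as.numeric(reg_tab[[v]])
  }
  reg <- stepwise_regression(reg_tab[!is.na(reg_tab[[response]]), ],
                             response, candidates)
  list(group_tests = gt, correlations = cors, regression = reg)
}

#' End-to-end cohort run
#'
#' Convenience wrapper: [cohort_features()] then [cohort_stats()].
#'
#' @inheritParams cohort_features
#' @inheritParams cohort_stats
#' @return List with `features` plus the elements of [cohort_stats()].
#' @export
run_cohort <- function(cohort, config = default_config(), candidates = NULL) {
  features <- cohort_features(cohort, config)
  c(list(features = features), cohort_stats(features, candidates))
}
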