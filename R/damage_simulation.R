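# Damage-simulation study driver: case definitions, outlier screening,
# leave-target-out reconstruction simulations, and report assembly/export.

#' Define a damage case
#'
#' @param name case label.
#' @param missing_indices non-empty set of 1-based landmark indices deleted
#'   under this case.
#' @return object of class \code{case_definition}.
#' @export
case_definition <- function(name, missing_indices) {
  missing_indices <- sort(unique(as.integer(missing_indices)))
  if (length(missing_indices) == 0L) stop("missing set must be non-empty")
  if (any(missing_indices < 1L)) stop("indices must be >= 1")
  structure(list(name = as.character(name),
                 missing_indices = missing_indices),
            class = "case_definition")
}

#' The three standard damage cases
#'
#' Case 1: landmarks \{1, 2\} (incomplete zygomatic process); Case 2:
#' landmarks \{4, 5, 7\} (damaged orbit); Case 3: semilandmarks \{16..21\}
#' (incomplete zygomatic body).
#'
#' @return list of three \code{case_definition} objects.
#' @export
default_cases <- function() {
  list(case_definition("Case1", c(1L, 2L)),
       case_definition("Case2", c(4L, 5L, 7L)),
       case_definition("Case3", 16:21))
}

#' Flag shape outliers relative to the consensus
#'
#' Computes every specimen's Procrustes distance to the consensus in the
#' common aligned space and flags those above Q3 + 1.5 IQR. Flagged
#' specimens are candidates for review of the digitization, never excluded
#' automatically.
#'
#' @param gpa_result a converged \code{gpa_result} with n >= 4.
#' @return data frame with \code{specimen_id}, \code{distance},
#'   \code{flagged}; the threshold is attached as attribute
#'   \code{"threshold"}.
#' @export
detect_outliers <- function(gpa_result) {
  stopifnot(inherits(gpa_result, "gpa_result"))
  n <- dim(gpa_result$aligned)[3]
  if (n < 4L) stop("outlier screening needs n >= 4")
  d <- vapply(seq_len(n), function(i)
    procrustes_distance(gpa_result$aligned[, , i], gpa_result$consensus,
                        "common_space"), numeric(1))
  qs <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  thr <- qs[2] + 1.5 * (qs[2] - qs[1])
  ids <- if (!is.null(gpa_result$meta)) gpa_result$meta$specimen_id
         else dimnames(gpa_result$aligned)[[3]] %||% as.character(seq_len(n))
  out <- data.frame(specimen_id = ids, distance = d, flagged = d > thr,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  out
}

#' Run the leave-target-out reconstruction simulation for one case
#'
#' Samples \code{n_targets} target specimens without replacement (seeded).
#' For each target: (1) the remaining specimens form the reference sample
#' and are aligned afresh (GPA + semilandmark sliding — strict
#' leave-one-out); (2) the target is standardized the same way every
#' specimen was before damage: superimposed onto the reference consensus
#' and its semilandmarks slid against it
#' (\code{\link{slide_to_reference}}), giving the true target coordinates;
#' (3) the case's landmarks are deleted from that configuration; (4) the RM
#' model is fitted on the reference and the target imputed; (5) the partial
#' Procrustes distances d(true, completed) and d(true, reference consensus)
#' are recorded. The target never influences the reference alignment,
#' consensus, or regression.
#'
#' @param dataset a complete \code{landmark_dataset}.
#' @param case a \code{case_definition}.
#' @param n_targets number of targets (<= n).
#' @param seed integer seed for target sampling.
#' @param targets optional explicit character vector of target ids
#'   (overrides sampling; used for shared-target designs).
#' @param slide_iterations,neighbors sliding parameters for the per-target
#'   reference alignment.
#' @return data frame of reconstruction records: \code{case_name},
#'   \code{target_id}, \code{d_true_pred}, \code{d_true_mean},
#'   \code{n_reference}.
#' @export
run_case <- function(dataset, case, n_targets, seed, targets = NULL,
                     slide_iterations = 3L, neighbors = 8L) {
  stopifnot(inherits(dataset, "landmark_dataset"),
            inherits(case, "case_definition"))
  n <- n_specimens(dataset)
  ids <- dataset$meta$specimen_id
  if (is.null(targets)) {
    if (n_targets > n) stop("n_targets exceeds sample size")
    targets <- with_seed(seed, sample(ids, n_targets))
  }
  k <- n_landmarks(dataset)
  if (any(case$missing_indices > k)) stop("case indices exceed k")
  records <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    target <- targets[ti]
    rec <- tryCatch({
      ref <- subset_dataset(dataset, setdiff(ids, target))
      g <- gpa(ref)
      g <- slide_semilandmarks(g, iterations = slide_iterations,
                               neighbors = neighbors)
      model <- fit_rm(g, case$missing_indices)
      raw_cfg <- get_configuration(dataset, target)
      true_coords <- slide_to_reference(raw_cfg$coords, g$consensus,
                                        dataset$roles,
                                        iterations = slide_iterations,
                                        neighbors = neighbors)
      true_cfg <- landmark_config(raw_cfg$specimen_id, true_coords,
                                  raw_cfg$roles, raw_cfg$population,
                                  raw_cfg$sex, raw_cfg$side)
      dc <- damaged_configuration(true_cfg, case$missing_indices)
      imp <- impute(model, dc)
      data.frame(case_name = case$name, target_id = target,
                 d_true_pred = procrustes_distance(true_cfg$coords,
                                                   imp$completed$coords,
                                                   "pairwise_opa"),
                 d_true_mean = procrustes_distance(true_cfg$coords,
                                                   g$consensus,
                                                   "pairwise_opa"),
                 n_reference = n_specimens(ref),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      stop("target '", target, "' (", case$name, "): ",
           conditionMessage(e), call. = FALSE)
    })
    records[[ti]] <- rec
  }
  do.call(rbind, records)
}

# Documented counter scheme deriving per-case seeds from the master seed,
# so each case is independently reproducible; kept below 2^31.
case_seed <- function(master_seed, case_index) {
  (as.integer(master_seed) + 104729L * as.integer(case_index)) %% .Machine$integer.max
}

#' Run the full damage-simulation study
#'
#' Runs \code{\link{run_case}} for every case (with per-case seeds derived
#' deterministically from the master seed), then assembles per-case
#' two-sample t-tests of d(true, predicted) against d(true, reference mean),
#' a one-way ANOVA of d(true, predicted) across cases, and Tukey HSD
#' pairwise comparisons.
#'
#' @param dataset a complete \code{landmark_dataset}.
#' @param cases list of \code{case_definition}s (default: the three standard
#'   cases).
#' @param n_targets targets per case (default 30).
#' @param seed master seed.
#' @param population_filter optional population name; the study is then run
#'   on that subsample (which must have at least \code{n_targets + 10}
#'   members).
#' @param shared_targets if \code{TRUE}, one target sample (drawn with the
#'   master seed) is shared by all cases; default \code{FALSE} (independent
#'   per-case samples).
#' @param t_variant t-test variant (default \code{"welch"}).
#' @param slide_iterations,neighbors passed to \code{\link{run_case}}.
#' @return object of class \code{study_report}: \code{records} (data frame),
#'   \code{case_tests} (per-case t-test summaries incl. paired supplement),
#'   \code{anova}, \code{tukey}, \code{config}.
#' @export
run_study <- function(dataset, cases = default_cases(), n_targets = 30L,
                      seed = 1L, population_filter = NULL,
                      shared_targets = FALSE, t_variant = "welch",
                      slide_iterations = 3L, neighbors = 8L) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (!is.null(population_filter)) {
    keep <- dataset$meta$population == population_filter
    if (sum(keep) < n_targets + 10L) {
      stop("population filter '", population_filter, "' leaves ",
           sum(keep), " specimens; need at least n_targets + 10 = ",
           n_targets + 10L)
    }
    dataset <- subset_dataset(dataset, which(keep))
  }
  shared <- if (shared_targets) {
    with_seed(seed, sample(dataset$meta$specimen_id, n_targets))
  } else NULL
  records <- do.call(rbind, lapply(seq_along(cases), function(ci) {
    run_case(dataset, cases[[ci]], n_targets,
             seed = case_seed(seed, ci), targets = shared,
             slide_iterations = slide_iterations, neighbors = neighbors)
  }))
  report_from_records(records,
                      config = list(seed = seed, n_targets = n_targets,
                                    cases = lapply(cases, unclass),
                                    population_filter = population_filter,
                                    shared_targets = shared_targets,
                                    t_variant = t_variant,
                                    slide_iterations = slide_iterations,
                                    neighbors = neighbors))
}

#' Recompute the study statistics from reconstruction records
#'
#' Every statistic of a \code{study_report} is a deterministic function of
#' the records table; this rebuilds the report (used for audit re-runs of an
#' exported \code{records.csv}).
#'
#' @param records data frame as emitted by \code{\link{run_case}}.
#' @param config configuration list echoed into the report.
#' @return a \code{study_report}.
#' @export
report_from_records <- function(records, config = list()) {
  case_names <- unique(records$case_name)
  t_variant <- config$t_variant %||% "welch"
  case_tests <- do.call(rbind, lapply(case_names, function(cn) {
    r <- records[records$case_name == cn, ]
    tt <- two_sample_t(r$d_true_pred, r$d_true_mean, t_variant)
    pt_res <- paired_t(r$d_true_pred, r$d_true_mean)
    data.frame(case_name = cn, t = tt$t, df = tt$df, p = tt$p,
               mean_d_true_pred = mean(r$d_true_pred),
               mean_d_true_mean = mean(r$d_true_mean),
               t_paired = pt_res$t, p_paired = pt_res$p,
               stringsAsFactors = FALSE)
  }))
  groups <- split(records$d_true_pred, factor(records$case_name, case_names))
  aov_res <- if (length(case_names) >= 2L) one_way_anova(groups) else NULL
  tukey <- if (length(case_names) >= 2L) tukey_hsd(groups) else NULL
  structure(list(records = records, case_tests = case_tests,
                 anova = aov_res, tukey = tukey, config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d records, %d cases x %d targets\n",
              nrow(x$records), length(unique(x$records$case_name)),
              x$config$n_targets %||% NA_integer_))
  print(x$case_tests, digits = 4)
  if (!is.null(x$anova)) {
    cat(sprintf("ANOVA: F(%d,%d) = %.2f, p = %.3g\n", x$anova$df_between,
                x$anova$df_within, x$anova$F, x$anova$p))
    print(x$tukey, digits = 4)
  }
  invisible(x)
}

#' Export a study report
#'
#' Writes \code{records.csv} (one row per reconstruction record),
#' \code{stats.json} (per-case t-tests, ANOVA, Tukey, config echo), and the
#' plot-data tables \code{scatter_data.csv} (per-target distances, both
#' comparison types wide) and \code{violin_data.csv} (distances long, by
#' case and comparison type).
#'
#' @param report a \code{study_report}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  stats <- list(
    cases = stats::setNames(lapply(seq_len(nrow(report$case_tests)), function(i) {
      r <- report$case_tests[i, ]
      list(t = r$t, df = r$df, p = r$p,
           mean_d_true_pred = r$mean_d_true_pred,
           mean_d_true_mean = r$mean_d_true_mean,
           t_paired = r$t_paired, p_paired = r$p_paired)
    }), report$case_tests$case_name),
    anova = if (!is.null(report$anova))
      list(F = report$anova$F, df1 = report$anova$df_between,
           df2 = report$anova$df_within, p = report$anova$p),
    tukey = if (!is.null(report$tukey))
      lapply(seq_len(nrow(report$tukey)), function(i)
        list(pair = report$tukey$pair[i], diff = report$tukey$diff[i],
             p = report$tukey$p[i])),
    config = report$config)
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  utils::write.csv(report$records[, c("case_name", "target_id",
                                      "d_true_pred", "d_true_mean")],
                   file.path(dir, "scatter_data.csv"), row.names = FALSE)
  long <- rbind(
    data.frame(case_name = report$records$case_name,
               comparison = "true_vs_predicted",
               distance = report$records$d_true_pred),
    data.frame(case_name = report$records$case_name,
               comparison = "true_vs_reference_mean",
               distance = report$records$d_true_mean))
  utils::write.csv(long, file.path(dir, "violin_data.csv"), row.names = FALSE)
  invisible(dir)
}
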