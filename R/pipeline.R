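#' Generate and write a phantom dataset
#'
#' Writes `n_cases` synthetic multimodal cases (four modality NIfTIs plus a
#' segmentation NIfTI per case) in BraTS-style layout, so the rest of the
#' pipeline can be exercised without external data.
#'
#' @param output_dir destination dataset root.
#' @param spec a [phantom_spec]; built from `...` when `NULL`.
#' @param ... arguments forwarded to [phantom_spec()] (e.g. `n_cases`,
#'   `seed`, `noise_sigma`).
#' @return Invisibly, a `data.frame` manifest with `case_id` and `path`.
#' @export
run_phantom <- function(output_dir, spec = NULL, ...) {
  if (is.null(spec)) spec <- phantom_spec(...)
  stopifnot(inherits(spec, "phantom_spec"))
  rows <- lapply(seq_len(spec$n_cases), function(i) {
    case <- generate_case(spec, i)
    data.frame(case_id = case$case_id, path = write_case(case, output_dir))
  })
  invisible(do.call(rbind, rows))
}

#' Preprocess a dataset with a named correction method
#'
#' Reads every case under `input_dir`, estimates the pseudo-energy
#' parameters over the requested scope, applies the chosen correction to
#' every modality channel, and writes the corrected cases (labels copied
#' through untouched) to `output_dir`. A JSON sidecar
#' (`preprocess_params.json`) records the method, the estimated
#' `epsilon_F`/`epsilon_b`, and every decision (scope, zero handling, gamma,
#' bins) for provenance. The pipeline is fully deterministic.
#'
#' @param input_dir dataset root in BraTS-style layout.
#' @param output_dir destination root.
#' @param method one of `"null"`, `"zscore"`, `"gamma"`, `"histeq3d"`,
#'   `"fd1"`, `"fd2"`.
#' @param stats_scope `"dataset"` pools the parameter estimate over all
#'   channels of all cases; `"volume"` estimates per channel volume.
#' @param exclude_zeros exclude the skull-stripped zero background from
#'   parameter estimation and preserve it as 0 in the output.
#' @param gamma exponent for `method = "gamma"`.
#' @param n_bins histogram bins for `method = "histeq3d"`.
#' @param target_hw optional in-plane size; when non-`NULL` every volume is
#'   passed through [rescale_to_input()] first (e.g. 240 -> 160).
#' @return Invisibly, the sidecar metadata as a list.
#' @export
run_preprocess <- function(input_dir, output_dir,
                           method = c("null", "zscore", "gamma", "histeq3d",
                                      "fd1", "fd2"),
                           stats_scope = c("dataset", "volume"),
                           exclude_zeros = TRUE, gamma = 0.6, n_bins = 256,
                           target_hw = NULL) {
  method <- match.arg(method)
  stats_scope <- match.arg(stats_scope)
  records <- find_cases(input_dir)
  if (length(records) == 0L) stop("no cases found", call. = FALSE)
  cases <- lapply(records, read_case)
  if (!is.null(target_hw)) {
    cases <- lapply(cases, function(case) {
      case$channels <- lapply(case$channels, rescale_to_input, target_hw)
      if (!is.null(case$labels))
        case$labels <- rescale_to_input(case$labels, target_hw, labels = TRUE)
      case
    })
  }

  params <- NULL
  if (method %in% c("zscore", "fd1", "fd2") && stats_scope == "dataset") {
    pool <- unlist(lapply(cases, `[[`, "channels"), recursive = FALSE)
    params <- estimate_fd_params(pool, stats_scope = "dataset",
                                 exclude_zeros = exclude_zeros)
  }
  for (case in cases) {
    case$channels <- lapply(case$channels, apply_correction, method = method,
                            params = params, gamma = gamma, n_bins = n_bins,
                            exclude_zeros = exclude_zeros)
    write_case(case, output_dir)
  }

  meta <- list(method = method, stats_scope = stats_scope,
               exclude_zeros = exclude_zeros,
               epsilon_F = if (!is.null(params)) params$epsilon_F,
               epsilon_b = if (!is.null(params)) params$epsilon_b,
               gamma = if (method == "gamma") gamma,
               n_bins = if (method == "histeq3d") n_bins,
               target_hw = target_hw, n_cases = length(cases),
               package_version = as.character(utils::packageVersion("fdcorrect")))
  jsonlite::write_json(meta, file.path(output_dir, "preprocess_params.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(meta)
}

region_row <- function(region, counts) {
  und <- function(f) tryCatch(f(counts), error = function(e) NA_real_)
  dice_den <- 2 * counts$tp + counts$fp + counts$fn
  data.frame(
    region = region, tp = counts$tp, tn = counts$tn, fp = counts$fp,
    fn = counts$fn,
    dice = if (dice_den == 0) 1 else 2 * counts$tp / dice_den,
    accuracy = und(accuracy), recall = und(recall), precision = und(precision),
    accuracy_reported = round_half_up(und(accuracy), 4),
    recall_reported = round_half_up(und(recall), 2),
    precision_reported = round_half_up(und(precision), 2))
}

#' Evaluate predicted segmentations against ground truth
#'
#' Matches cases by id between two BraTS-style trees of segmentation label
#' volumes, decomposes each into the nested WT/TC/ET regions, pools the
#' voxel-wise confusion counts over all cases per region, and reports the
#' pooled dice, accuracy, recall and precision (full precision plus
#' printed-table rounding). Indicators whose denominator vanishes are
#' reported as `NA` (undefined); an empty region in both prediction and
#' truth scores dice 1 by convention.
#'
#' @param pred_dir,truth_dir dataset roots whose cases carry `_seg` label
#'   volumes.
#' @param regions subset of `c("WT", "TC", "ET")`.
#' @param output_csv,output_json optional report destinations.
#' @return A `data.frame`, one row per region, in confusion-matrix table
#'   layout (`region`, `tp`, `tn`, `fp`, `fn`, `dice`, `accuracy`, `recall`,
#'   `precision`, and `*_reported` columns).
#' @export
run_evaluate <- function(pred_dir, truth_dir, regions = c("WT", "TC", "ET"),
                         output_csv = NULL, output_json = NULL) {
  regions <- match.arg(regions, several.ok = TRUE)
  read_labels <- function(dir) {
    recs <- find_cases(dir)
    labs <- lapply(recs, function(r) {
      if (is.null(r$label_path))
        stop(sprintf("case '%s' has no segmentation volume", r$case_id),
             call. = FALSE)
      read_case(r)$labels
    })
    names(labs) <- vapply(recs, `[[`, character(1), "case_id")
    labs
  }
  pred <- read_labels(pred_dir)
  truth <- read_labels(truth_dir)
  unmatched <- c(setdiff(names(pred), names(truth)),
                 setdiff(names(truth), names(pred)))
  if (length(unmatched) > 0L)
    stop(sprintf("unmatched case ids: %s",
                 paste(sort(unique(unmatched)), collapse = ", ")),
         call. = FALSE)

  rows <- lapply(regions, function(reg) {
    per_case <- lapply(names(truth), function(id) {
      confusion_counts(label_decompose(pred[[id]])[[reg]],
                       label_decompose(truth[[id]])[[reg]])
    })
    region_row(reg, pool_counts(per_case))
  })
  report <- do.call(rbind, rows)
  if (!is.null(output_csv))
    utils::write.csv(report, output_csv, row.names = FALSE)
  if (!is.null(output_json))
    jsonlite::write_json(report, output_json, dataframe = "rows", na = "null",
                         digits = NA)
  report
}

#' Gamma grid search over a phantom or real dataset
#'
#' Runs [gamma_sweep()] with the default evaluator: gamma-correct every
#' channel, segment with [threshold_segmenter()], and score the pooled
#' whole-tumor dice against the label volumes.
#'
#' @param input_dir dataset root with `_seg` label volumes.
#' @param grid candidate exponents.
#' @param threshold channel-maximum cut handed to the segmenter.
#' @return As [gamma_sweep()]: `best_gamma` plus the per-gamma score table.
#' @export
run_gamma_sweep <- function(input_dir,
                            grid = c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.5, 2),
                            threshold = 0.5) {
  cases <- lapply(find_cases(input_dir), read_case)
  volumes <- lapply(cases, `[[`, "channels")
  labels <- lapply(cases, `[[`, "labels")
  if (any(vapply(labels, is.null, logical(1))))
    stop("all cases need segmentation volumes", call. = FALSE)
  evaluator <- function(pre, labs) {
    counts <- pool_counts(Map(function(chs, lab) {
      confusion_counts(threshold_segmenter(chs, threshold),
                       label_decompose(lab)$WT)
    }, pre, labs))
    den <- 2 * counts$tp + counts$fp + counts$fn
    if (den == 0) 1 else 2 * counts$tp / den
  }
  gamma_sweep(volumes, labels, evaluator, grid = grid)
}
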