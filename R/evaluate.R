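#' Jaccard coefficient (intersection over union) of two masks
#'
#' `|A & B| / |A | B|` over nonzero pixels; 1 for identical nonempty masks,
#' 0 for disjoint ones.  Undefined (error) when both masks are empty.
#'
#' @param a,b masks of the same shape with entries in \{0, 255\}.
#' @return numeric in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  assert_mask(a); assert_mask(b)
  if (!all(dim(a) == dim(b)))
    stop("masks must have the same shape", call. = FALSE)
  fa <- a != 0L; fb <- b != 0L
  uni <- sum(fa | fb)
  if (uni == 0L)
    stop("undefined-IoU: both masks are empty", call. = FALSE)
  sum(fa & fb) / uni
}

#' Evaluate the pipeline on a phantom suite
#'
#' Runs [forehead_segment()] on every frame (with the frame's true glasses
#' flag), scores the forehead mask against the analytic ground truth with
#' [jaccard()], and summarises.  Per-frame failures are recorded as
#' `failed:<stage>` and excluded from the IoU statistics but always counted;
#' a failing frame never aborts the batch.
#'
#' @param suite result of [generate_suite()], or a list with `phantoms` and
#'   `manifest`.
#' @param shift_fraction,quantile pipeline parameters, see
#'   [forehead_segment()].
#' @param csv optional path for the per-frame records CSV.
#' @param .predict segmentation function `(frame, has_glasses)` returning an
#'   object with `mask`, `mean_temp_c` and `geometry`; defaults to the full
#'   pipeline.  Injectable for harness tests.
#' @return list of class `thermoface_eval` with `records` (data.frame:
#'   frame_id, status, jaccard, mean_temp_c, beta_deg) and `summary`
#'   (mean/median/min IoU over ok frames, counts).
#' @export
evaluate_batch <- function(suite, shift_fraction = 0.20, quantile = 0.10,
                           csv = NULL, .predict = NULL) {
  if (is.null(.predict))
    .predict <- function(frame, has_glasses)
      forehead_segment(frame, has_glasses, shift_fraction = shift_fraction,
                       quantile = quantile)
  phantoms <- suite$phantoms
  ids <- suite$manifest$frame_id
  rec <- data.frame(frame_id = ids, status = NA_character_,
                    jaccard = NA_real_, mean_temp_c = NA_real_,
                    beta_deg = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    res <- tryCatch(
      .predict(ph$frame, ph$truth$spec$has_glasses),
      thermoface_stage_error = function(e) e,
      error = function(e) e)
    if (inherits(res, "error")) {
      stage <- if (!is.null(res$stage)) res$stage else "unknown"
      rec$status[i] <- paste0("failed:", stage)
    } else {
      rec$status[i] <- "ok"
      rec$jaccard[i] <- jaccard(res$mask, ph$truth$forehead_mask)
      rec$mean_temp_c[i] <- res$mean_temp_c
      rec$beta_deg[i] <- res$geometry$beta * 180 / pi
    }
  }
  ok <- rec$status == "ok"
  summ <- list(n = nrow(rec), n_ok = sum(ok), n_failed = sum(!ok),
               mean_iou = if (any(ok)) mean(rec$jaccard[ok]) else NA_real_,
               median_iou = if (any(ok)) stats::median(rec$jaccard[ok]) else NA_real_,
               min_iou = if (any(ok)) min(rec$jaccard[ok]) else NA_real_)
  if (!is.null(csv)) utils::write.csv(rec, csv, row.names = FALSE)
  structure(list(records = rec, summary = summ), class = "thermoface_eval")
}

#' @export
print.thermoface_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Batch evaluation: %d frames, %d ok, %d failed\n",
              s$n, s$n_ok, s$n_failed))
  if (s$n_ok > 0)
    cat(sprintf("  Jaccard (ok frames): mean %.4f, median %.4f, min %.4f\n",
                s$mean_iou, s$median_iou, s$min_iou))
  invisible(x)
}
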