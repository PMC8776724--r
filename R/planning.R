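#' Future liver remnant (FLR) for a resection plan
#'
#' FLR% = 100 x (total - sum of removed segment volumes) / total, judged
#' against a parenchyma-dependent safe lower limit: 20% for healthy
#' parenchyma, 30% with steatosis, 40% with fibrosis or cirrhosis.
#' Thresholds are configuration, not hard-coded clinical advice.
#'
#' @param report a `segment_report` with all nine segment volumes.
#' @param remove segments to resect: codes (1, 2, ..., 41, 42) or names
#'   ("4a", "4b"); a bare "4" expands to both 4a and 4b.
#' @param status parenchyma status: "healthy", "steatosis" or
#'   "fibrosis_cirrhosis".
#' @param thresholds named percentage thresholds per status.
#' @return an `flr_result`: flr_percent, threshold_percent, adequate,
#'   remnant_volume_ml, total_volume_ml, removed.
#' @examples
#' rep <- data.frame(segment = c(couinaud::segment_names(), "whole_liver"),
#'                   volume_ml = c(rep(100, 9), 900))
#' class(rep) <- c("segment_report", "data.frame")
#' flr(rep, remove = c("1", "4", "5", "6", "7", "8"), status = "healthy")
#' @export
flr <- function(report, remove, status = c("healthy", "steatosis", "fibrosis_cirrhosis"),
                thresholds = c(healthy = 20, steatosis = 30, fibrosis_cirrhosis = 40)) {
  status <- match.arg(status)
  codes <- normalize_codes(remove)
  seg_vol <- report_volume(report, segment_names())
  total <- sum(seg_vol)
  if (total <= 0) cn_stop("total liver volume is zero", "couinaud_zero_volume")
  removed_vol <- sum(seg_vol[match(codes, segment_codes())])
  flr_pct <- 100 * (total - removed_vol) / total
  thr <- unname(thresholds[status])
  structure(list(flr_percent = flr_pct,
                 threshold_percent = thr,
                 adequate = flr_pct >= thr,
                 remnant_volume_ml = total - removed_vol,
                 total_volume_ml = total,
                 removed = segment_name(codes),
                 parenchyma_status = status),
            class = "flr_result")
}

#' @export
print.flr_result <- function(x, ...) {
  cat(sprintf("FLR %.2f%% (remnant %.1f mL of %.1f mL)\n",
              x$flr_percent, x$remnant_volume_ml, x$total_volume_ml))
  cat(sprintf("  removing segments: %s\n", paste(x$removed, collapse = ", ")))
  cat(sprintf("  parenchyma %s, threshold %.0f%%: %s\n", x$parenchyma_status,
              x$threshold_percent, if (x$adequate) "ADEQUATE" else "INADEQUATE"))
  invisible(x)
}

#' Catalogue of canonical anatomical resections
#'
#' @return named list of removed-segment sets: right and extended right
#'   hepatectomy, left hepatectomy, left lateral sectionectomy, the combined
#'   segment 5+8 segmentectomy, and each single segmentectomy.
#' @export
resection_catalogue <- function() {
  cat <- list(
    right_hepatectomy = c("5", "6", "7", "8"),
    extended_right_hepatectomy = c("1", "4a", "4b", "5", "6", "7", "8"),
    left_hepatectomy = c("2", "3", "4a", "4b"),
    left_lateral_sectionectomy = c("2", "3"),
    segmentectomy_5_8 = c("5", "8"))
  singles <- stats::setNames(as.list(segment_names()),
                             paste0("segmentectomy_", segment_names()))
  c(cat, singles)
}

#' FLR for every catalogued resection
#'
#' @inheritParams flr
#' @param catalogue named list of removed-segment sets;
#'   default [resection_catalogue()].
#' @return data frame: plan, removed, flr_percent, threshold_percent, adequate.
#' @export
enumerate_plans <- function(report, status = c("healthy", "steatosis", "fibrosis_cirrhosis"),
                            catalogue = resection_catalogue()) {
  status <- match.arg(status)
  rows <- lapply(names(catalogue), function(nm) {
    r <- flr(report, catalogue[[nm]], status)
    data.frame(plan = nm, removed = paste(r$removed, collapse = "+"),
               flr_percent = r$flr_percent,
               threshold_percent = r$threshold_percent,
               adequate = r$adequate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
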