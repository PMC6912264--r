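# Consensus differential-expression calling across the six datasets: a
# protein passes a dataset when nominal p < alpha and |FC| > fc_abs (both
# strict); it is called DE for a contrast when it passes dataset 1, or
# passes more than 3 of the 5 imputed datasets ("more than 3" = at least
# min_imputed_pass = 4) with a coherent sign.

#' Consensus thresholds
#'
#' @param alpha Nominal p-value threshold (strict, default 0.05).
#' @param fc_abs Absolute linear fold-change threshold (strict, default 1.5).
#' @param min_imputed_pass Minimum number of imputed datasets that must pass
#'   (default 4 of 5, the literal reading of "more than 3").
#' @return A `de_thresholds` object.
#' @export
de_thresholds <- function(alpha = 0.05, fc_abs = 1.5, min_imputed_pass = 4L) {
  t <- list(alpha = check_number(alpha, "alpha"),
            fc_abs = check_number(fc_abs, "fc_abs"),
            min_imputed_pass = check_count(min_imputed_pass, "min_imputed_pass"))
  if (t$alpha <= 0 || t$alpha >= 1) stop_config("alpha", "must be in (0, 1)")
  if (t$fc_abs <= 1) stop_config("fc_abs", "must be > 1")
  structure(t, class = "de_thresholds")
}

med_or_na <- function(v) if (length(v)) stats::median(v) else NA_real_

#' Consensus differential-expression calls
#'
#' For each (protein, contrast): a dataset "passes" iff `p < alpha` and
#' `|FC| > fc_abs` (strict inequalities; an unevaluable dataset-1 result
#' counts as not passing). The protein is called DE when dataset 1 passes,
#' or when at least `min_imputed_pass` imputed datasets pass *with the same
#' sign* (sign-incoherent votes are not called, with a message). Direction is
#' the sign of the median log2 difference across passing datasets; the
#' representative fold change and p-value are medians across the imputed
#' datasets, with the dataset-1 values reported alongside when defined.
#'
#' @param results Contrast result table from [analyze_collection()]; must
#'   cover every dataset for every (protein, contrast).
#' @param thresholds [de_thresholds()].
#' @return Data frame with one row per (protein, contrast): `accession`,
#'   `contrast`, `de`, `direction` (up/down/undefined), `route` (dataset1 /
#'   imputed_consensus / both / none), `n_imputed_pass`, `dataset1_pass`,
#'   `dataset1_evaluable`, `rep_fc`, `rep_p`, `dataset1_fc`, `dataset1_p`.
#' @export
call_de <- function(results, thresholds = de_thresholds()) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  needed <- c("accession", "contrast", "dataset", "kind", "p", "delta_log2", "fc")
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols)) {
    stop("validation error: results table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  datasets <- sort(unique(results$dataset))
  cover <- table(results$accession, results$contrast)
  if (length(unique(as.vector(cover))) != 1L ||
      as.vector(cover)[1] != length(datasets)) {
    stop("validation error: inconsistent dataset coverage across (protein, contrast)",
         call. = FALSE)
  }
  if (sum(results$kind == "missing_neglect" & results$dataset == 1L) == 0) {
    stop("validation error: dataset 1 (missing_neglect) absent", call. = FALSE)
  }

  pass <- !is.na(results$p) & results$p < thresholds$alpha &
    !is.na(results$fc) & abs(results$fc) > thresholds$fc_abs
  results$pass <- pass

  key <- interaction(results$accession, results$contrast, drop = TRUE)
  pieces <- lapply(split(results, key), function(r) {
    d1 <- r[r$dataset == 1L, , drop = FALSE]
    imp <- r[r$dataset != 1L, , drop = FALSE]
    d1_eval <- !is.na(d1$p)
    d1_pass <- isTRUE(d1$pass)
    ipass <- imp[imp$pass, , drop = FALSE]
    n_up <- sum(ipass$delta_log2 > 0)
    n_dn <- sum(ipass$delta_log2 < 0)
    imputed_call <- max(n_up, n_dn) >= thresholds$min_imputed_pass
    n_pass <- nrow(ipass)
    if (!imputed_call && n_pass >= thresholds$min_imputed_pass) {
      message(sprintf("sign-incoherent imputed votes for %s (%s): not called",
                      r$accession[1], r$contrast[1]))
    }
    de <- d1_pass || imputed_call
    passing <- rbind(if (d1_pass) d1, ipass)
    med_delta <- med_or_na(passing$delta_log2)
    direction <- if (!de || is.na(med_delta) || med_delta == 0) {
      "undefined"
    } else if (med_delta > 0) "up" else "down"
    route <- if (d1_pass && imputed_call) {
      "both"
    } else if (d1_pass) {
      "dataset1"
    } else if (imputed_call) "imputed_consensus" else "none"
    data.frame(accession = r$accession[1], contrast = r$contrast[1],
               de = de, direction = direction, route = route,
               n_imputed_pass = n_pass, dataset1_pass = d1_pass,
               dataset1_evaluable = d1_eval,
               rep_fc = med_or_na(imp$fc), rep_p = med_or_na(imp$p),
               dataset1_fc = d1$fc, dataset1_p = d1$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$contrast, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summaries of consensus calls
#'
#' Per-contrast counts of DE proteins, up/down split and down-regulated
#' fraction, plus the union list of proteins DE in at least one contrast
#' (the cross-contrast union that downstream clustering operates on).
#'
#' @param calls Output of [call_de()].
#' @return List with `per_contrast` (data frame: contrast, n_de, n_up,
#'   n_down, fraction_down) and `union` (character vector of accessions).
#' @export
summarize_calls <- function(calls) {
  per <- do.call(rbind, lapply(split(calls, calls$contrast), function(cc) {
    n_de <- sum(cc$de)
    n_up <- sum(cc$de & cc$direction == "up")
    n_down <- sum(cc$de & cc$direction == "down")
    data.frame(contrast = cc$contrast[1], n_de = n_de, n_up = n_up,
               n_down = n_down,
               fraction_down = if (n_de > 0) n_down / n_de else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_contrast = per,
       union = sort(unique(calls$accession[calls$de])))
}
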