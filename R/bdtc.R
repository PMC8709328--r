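#' Default rule table of the binary decision tree
#'
#' The third step of the decision tree assigns a lesion type from the
#' arterial enhancement pattern, conditioned on the first two decisions
#' (cirrhosis, washout). The table reconstructs the standard CEUS reading of
#' each pattern: with washout, hyper-enhancement reads as HCC (whether or
#' not the liver is cirrhotic), rim enhancement as metastasis, and rim-like
#' enhancement with central hypo-enhancement as cholangiocarcinoma; without
#' washout, peripheral nodular enhancement reads as haemangioma, centrifugal
#' hyper-enhancement as FNH, peripheral enhancement with septa as abscess,
#' and iso-enhancement as a regenerative nodule in a cirrhotic liver or a
#' focal fatty change otherwise. Keys not present in the table yield an
#' indeterminate type.
#'
#' The table is plain data (a data frame), so alternative readings of the
#' tree - for example routing non-cirrhotic hyper-enhancing washout lesions
#' to adenoma rather than HCC - can be supplied to [bdtc_classify()] without
#' touching code, or serialized to/from JSON with [write_rule_table()].
#'
#' @return data frame with columns `cirrhotic` (logical), `washout`
#'   (logical), `pattern`, `type`.
#' @seealso [bdtc_classify()], [enhancement_patterns()]
#' @export
default_rule_table <- function() {
  rt <- rbind(
    data.frame(cirrhotic = c(TRUE, FALSE), washout = TRUE,
               pattern = "hyper-enhancement", type = "HCC"),
    expand.grid(cirrhotic = c(TRUE, FALSE), washout = TRUE,
                pattern = "rim enhancement", type = "metastasis"),
    expand.grid(cirrhotic = c(TRUE, FALSE), washout = TRUE,
                pattern = "rim-like with central hypo-enhancement",
                type = "cholangiocarcinoma"),
    expand.grid(cirrhotic = c(TRUE, FALSE), washout = FALSE,
                pattern = "peripheral nodular enhancement",
                type = "haemangioma"),
    expand.grid(cirrhotic = c(TRUE, FALSE), washout = FALSE,
                pattern = "centrifugal hyper-enhancement", type = "FNH"),
    expand.grid(cirrhotic = c(TRUE, FALSE), washout = FALSE,
                pattern = "peripheral enhancement with septa",
                type = "abscess"),
    data.frame(cirrhotic = TRUE, washout = FALSE,
               pattern = "iso-enhancement", type = "regenerative nodule"),
    data.frame(cirrhotic = FALSE, washout = FALSE,
               pattern = "iso-enhancement", type = "focal fatty alteration")
  )
  rt$pattern <- as.character(rt$pattern)
  rt$type <- as.character(rt$type)
  rownames(rt) <- NULL
  rt
}

#' High-sensitivity malignancy screen (elastography OR washout)
#'
#' The two-feature screening rule that combines the first two steps of the
#' pipeline: a lesion is called malignancy-suspect when the liver is
#' cirrhotic (F4) OR the lesion TIC shows washout (AREA at or below the
#' cutoff). An OR rule trades specificity for sensitivity, which is its
#' purpose as a screen.
#'
#' @param cirrhotic logical, liver fibrosis stage F4.
#' @param lesion_area lesion AREA, dB.
#' @param cutoff washout cutoff, dB.
#' @return logical.
#' @export
#' @examples
#' mpus_malignancy(TRUE, -5)    # cirrhotic arm
#' mpus_malignancy(FALSE, -25)  # washout arm
#' mpus_malignancy(FALSE, -5)   # neither
mpus_malignancy <- function(cirrhotic, lesion_area, cutoff = -19.3) {
  stopifnot(is.logical(cirrhotic))
  cirrhotic | washout_flag(lesion_area, cutoff)
}

#' Classify one lesion with the three-step binary decision tree
#'
#' Applies, in order: (1) the fibrosis branch (cirrhotic F4 vs below); (2)
#' the TIC branch (washout iff lesion AREA at or below `cutoff`); (3) when
#' an arterial pattern is available, a type lookup in the rule table keyed
#' by (cirrhotic, washout, pattern). The malignancy call is driven by the
#' washout branch - washout means malignant, no washout benign - while the
#' fibrosis branch conditions the type assignment (e.g. iso-enhancement
#' without washout reads as regenerative nodule only in a cirrhotic liver).
#' A missing pattern or an absent key yields type `"indeterminate"`; the
#' malignancy call is still made, mirroring a reader who can call washout on
#' every lesion but type only a subset.
#'
#' @param cirrhotic logical.
#' @param lesion_area lesion AREA, dB (used when `washout` is NULL).
#' @param pattern arterial pattern label, or `NA` when unavailable.
#' @param cutoff washout cutoff, dB.
#' @param rule_table rule table as from [default_rule_table()].
#' @param washout optional precomputed washout flag overriding the AREA
#'   comparison.
#' @return list with `washout`, `predicted_malignant`, `predicted_type` and
#'   `path` (character vector of the branches taken, length 2 without a
#'   pattern, 3 with one).
#' @export
#' @examples
#' bdtc_classify(TRUE, -25, "hyper-enhancement")    # malignant, HCC
#' bdtc_classify(FALSE, -5, "peripheral nodular enhancement")
bdtc_classify <- function(cirrhotic, lesion_area = NULL, pattern = NA,
                          cutoff = -19.3,
                          rule_table = default_rule_table(),
                          washout = NULL) {
  stopifnot(is.logical(cirrhotic), length(cirrhotic) == 1L)
  if (is.null(washout)) {
    if (is.null(lesion_area)) stop("need 'lesion_area' or 'washout'")
    washout <- washout_flag(lesion_area, cutoff)
  }
  if (!is.na(pattern) && !pattern %in% enhancement_patterns()$pattern)
    stop("invalid enhancement pattern label: ", pattern)

  path <- c(if (cirrhotic) "fibrosis:F4" else "fibrosis:<F4",
            if (washout) "tic:washout" else "tic:no-washout")
  predicted_malignant <- washout

  if (is.na(pattern)) {
    type <- "indeterminate"
  } else {
    path <- c(path, paste0("pattern:", pattern))
    hit <- rule_table$cirrhotic == cirrhotic &
      rule_table$washout == washout & rule_table$pattern == pattern
    type <- if (any(hit)) rule_table$type[which(hit)[1]] else "indeterminate"
  }
  list(washout = washout, predicted_malignant = predicted_malignant,
       predicted_type = type, path = path)
}

#' Classify a whole cohort
#'
#' Fits the washout model to every lesion TIC of a cohort, derives the AREA
#' statistic, and runs the decision tree on each lesion. When the cohort
#' carries precomputed `area_lesion` values and `use_fitted = FALSE`, the
#' fitting stage is skipped and the stored AREAs are used directly.
#'
#' @param cohort an `mpus_cohort` (see [sample_cohort()]) or a list with
#'   `lesions` and `tic` components in the same schema.
#' @param cutoff washout cutoff, dB.
#' @param rule_table rule table, see [default_rule_table()].
#' @param use_fitted fit the washout model to the TIC series (default); if
#'   `FALSE`, use the cohort's stored `area_lesion`.
#' @return data frame of class `bdtc_results` with one row per lesion:
#'   `lesion_id`, `area_lesion` (the AREA actually used), `washout`,
#'   `predicted_malignant`, `predicted_type`, `path` (branches joined by
#'   `" -> "`).
#' @export
classify_cohort <- function(cohort, cutoff = -19.3,
                            rule_table = default_rule_table(),
                            use_fitted = TRUE) {
  les <- cohort$lesions
  areas <- if (use_fitted) {
    fits <- quantify_cohort(cohort, roi = "lesion")
    fits$area[match(les$lesion_id, fits$lesion_id)]
  } else {
    if (is.null(les$area_lesion))
      stop("cohort has no stored 'area_lesion'; set use_fitted = TRUE")
    les$area_lesion
  }
  rows <- lapply(seq_len(nrow(les)), function(i) {
    r <- bdtc_classify(les$cirrhotic[i], areas[i],
                       pattern = if (is.na(les$pattern[i]) ||
                                     !nzchar(les$pattern[i])) NA
                                 else les$pattern[i],
                       cutoff = cutoff, rule_table = rule_table)
    data.frame(lesion_id = les$lesion_id[i], area_lesion = areas[i],
               washout = r$washout,
               predicted_malignant = r$predicted_malignant,
               predicted_type = r$predicted_type,
               path = paste(r$path, collapse = " -> "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bdtc_results", "data.frame")
  out
}

#' Fit the washout model to every TIC of a cohort
#'
#' @param cohort an `mpus_cohort` or list with a `tic` long table.
#' @param roi which ROIs to fit: `"lesion"`, `"parenchyma"` or `"both"`.
#' @param area_mode passed to [fit_washout()].
#' @return data frame with one row per (lesion, ROI): `lesion_id`, `roi`,
#'   `A`, `B`, `k`, `gradient0`, `ttopk`, `area`, `mse`, `converged`.
#' @export
quantify_cohort <- function(cohort, roi = c("both", "lesion", "parenchyma"),
                            area_mode = c("fitted", "raw")) {
  roi <- match.arg(roi)
  area_mode <- match.arg(area_mode)
  tic <- cohort$tic
  keep <- if (roi == "both") rep(TRUE, nrow(tic)) else tic$roi == roi
  tic <- tic[keep, , drop = FALSE]
  parts <- split(tic, list(tic$lesion_id, tic$roi), drop = TRUE)
  rows <- lapply(parts, function(d) {
    d <- d[order(d$t_seconds), , drop = FALSE]
    fit <- fit_washout(tic_series(d$t_seconds, d$intensity_db,
                                  lesion_id = d$lesion_id[1], roi = d$roi[1]),
                       area_mode = area_mode)
    data.frame(lesion_id = d$lesion_id[1], roi = d$roi[1],
               A = fit$coefficients[["A"]], B = fit$coefficients[["B"]],
               k = fit$coefficients[["k"]], gradient0 = fit$gradient0,
               ttopk = fit$ttopk, area = fit$area, mse = fit$mse,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$lesion_id, out$roi), , drop = FALSE]
}
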