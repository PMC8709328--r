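#' Reference lesion types and their malignancy map
#'
#' The twelve reference diagnoses encountered in the inconclusive focal liver
#' lesion cohort, each with its conventional malignancy status and the arterial
#' enhancement pattern used when simulating it. Hepatocellular carcinoma (HCC),
#' metastasis and cholangiocarcinoma are malignant; all remaining types,
#' including hepatocellular adenoma, default to benign. Because adenomas carry
#' a real (if small) malignant-transformation risk and published series differ
#' in how they score them, the malignancy of any type can be overridden.
#'
#' Types without a canonical arterial-phase row in the enhancement-pattern
#' table (e.g. regenerative nodule, fatty free area) are simulated with the
#' pattern a sonographer would most plausibly read for them; see the methods
#' vignette for the rationale behind each assignment.
#'
#' @param malignant_override named logical vector overriding the malignancy of
#'   individual types, e.g. `c(adenoma = TRUE)`. Names must be lesion-type
#'   labels.
#' @return A data frame with one row per lesion type and columns `type`
#'   (label), `malignant` (logical) and `pattern` (arterial enhancement
#'   pattern used in simulation).
#' @seealso [enhancement_patterns()], [default_composition()]
#' @export
#' @examples
#' lesion_types()
#' lesion_types(c(adenoma = TRUE))
lesion_types <- function(malignant_override = NULL) {
  tab <- data.frame(
    type = c("HCC", "metastasis", "cholangiocarcinoma",
             "haemangioma", "regenerative nodule", "focal fatty alteration",
             "fatty free area", "abscess", "adenoma", "complex biliary cyst",
             "parenchymal infarction", "vascular abnormality"),
    malignant = c(TRUE, TRUE, TRUE,
                  FALSE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    pattern = c("hyper-enhancement", "rim enhancement",
                "rim-like with central hypo-enhancement",
                "peripheral nodular enhancement", "iso-enhancement",
                "iso-enhancement", "iso-enhancement",
                "peripheral enhancement with septa", "hyper-enhancement",
                "peripheral enhancement with septa", "iso-enhancement",
                "centrifugal hyper-enhancement"),
    stringsAsFactors = FALSE
  )
  if (!is.null(malignant_override)) {
    if (is.null(names(malignant_override)) || !is.logical(malignant_override))
      stop("'malignant_override' must be a named logical vector")
    bad <- setdiff(names(malignant_override), tab$type)
    if (length(bad))
      stop("unknown lesion type(s) in override: ", paste(bad, collapse = ", "))
    tab$malignant[match(names(malignant_override), tab$type)] <-
      unname(malignant_override)
  }
  tab
}

#' Arterial-phase enhancement patterns
#'
#' The seven arterial-phase (10-20 to 30-45 s after bolus) enhancement
#' patterns read from parametric imaging, with the lesion diagnosis each one
#' typically suggests in daily CEUS practice. These labels are the vocabulary
#' of the third step of the decision tree.
#'
#' @return A data frame with columns `pattern` and `typical_lesion`.
#' @seealso [default_rule_table()]
#' @export
enhancement_patterns <- function() {
  data.frame(
    pattern = c("peripheral nodular enhancement",
                "centrifugal hyper-enhancement",
                "peripheral enhancement with septa",
                "rim enhancement",
                "hyper-enhancement",
                "rim-like with central hypo-enhancement",
                "iso-enhancement"),
    typical_lesion = c("haemangioma", "FNH", "abscess", "metastasis",
                       "HCC", "cholangiocarcinoma", "focal fatty change"),
    stringsAsFactors = FALSE
  )
}

#' Default cohort census
#'
#' Lesion-type counts of the default simulated cohort: 91 inconclusive focal
#' liver lesions dominated by HCC (34) and metastases (13), with the remainder
#' spread over ten benign or rare diagnoses.
#'
#' @return A named integer vector of counts over the twelve lesion types,
#'   summing to 91.
#' @export
#' @examples
#' comp <- default_composition()
#' sum(comp)  # 91
default_composition <- function() {
  c("HCC" = 34L, "metastasis" = 13L, "haemangioma" = 7L,
    "regenerative nodule" = 7L, "focal fatty alteration" = 5L,
    "fatty free area" = 3L, "cholangiocarcinoma" = 4L, "abscess" = 2L,
    "adenoma" = 5L, "complex biliary cyst" = 4L,
    "parenchymal infarction" = 5L, "vascular abnormality" = 2L)
}
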