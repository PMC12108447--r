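#' Bundled breakpoint table
#'
#' A small, editable breakpoint fixture (drug x organism) used as the
#' surrogate MIC when no organism was isolated, in the spirit of CLSI
#' susceptible breakpoints. The values are bundled, synthetic defaults with
#' a provenance tag, not a normative CLSI excerpt; replace the file (or pass
#' your own table) for real analyses. Pairs absent from the table are
#' treated as unresolvable (this also covers intrinsic resistance, e.g.
#' ampicillin against Pseudomonas aeruginosa).
#'
#' @param path Optional path to a CSV with columns `drug`, `organism`,
#'   `breakpoint_mg_L`, `source_tag`; defaults to the bundled file.
#' @return Tibble with those four columns.
#' @export
default_breakpoints <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "breakpoints.csv", package = "tdmattain")
  }
  bp <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("drug", "organism", "breakpoint_mg_L") %in% names(bp)),
            all(bp$breakpoint_mg_L > 0))
  bp
}

#' Resolve the effective MIC for an infection episode
#'
#' Applies the study's MIC hierarchy: with isolates present, the highest
#' measured MIC across all isolates of the episode is used (polymicrobial
#' rule); cefazolin against methicillin-susceptible S. aureus is targeted at
#' a fixed 2 mg/L breakpoint regardless of the measured value; with no
#' growth, the breakpoint for the suspected causative pathogen stands in.
#'
#' @param isolates Data frame with columns `organism` and `mic_mg_L`
#'   (possibly zero rows), or `NULL`.
#' @param drug Drug name.
#' @param suspected_pathogen Organism name used for the breakpoint fallback;
#'   may be `NA`/empty when isolates exist.
#' @param breakpoints Breakpoint table, as [default_breakpoints()].
#' @param mssa_cefazolin_rule Apply the fixed 2 mg/L cefazolin/MSSA target
#'   (default `TRUE`). When it fires it overrides a measured MIC.
#' @return List of class `"effective_mic"`: `value` (mg/L) and `provenance`
#'   (one of `"measured_max"`, `"breakpoint"`, `"mssa_cefazolin_rule"`).
#' @export
#' @examples
#' effective_mic(data.frame(organism = c("Escherichia coli",
#'                                       "Pseudomonas aeruginosa"),
#'                          mic_mg_L = c(2, 8)), "cefepime")
effective_mic <- function(isolates, drug, suspected_pathogen = NA_character_,
                          breakpoints = default_breakpoints(),
                          mssa_cefazolin_rule = TRUE) {
  has_isolates <- !is.null(isolates) && nrow(isolates) > 0L
  if (has_isolates) {
    if (any(isolates$mic_mg_L <= 0)) {
      stop("isolate MICs must be > 0", call. = FALSE)
    }
    if (mssa_cefazolin_rule && drug == "cefazolin" &&
        any(grepl("Staphylococcus aureus", isolates$organism,
                  fixed = TRUE))) {
      return(structure(list(value = 2, provenance = "mssa_cefazolin_rule"),
                       class = "effective_mic"))
    }
    return(structure(list(value = max(isolates$mic_mg_L),
                          provenance = "measured_max"),
                     class = "effective_mic"))
  }
  if (is.na(suspected_pathogen) || !nzchar(suspected_pathogen)) {
    stop("no isolates and no suspected pathogen: MIC unresolvable for ",
         drug, call. = FALSE)
  }
  hit <- breakpoints$drug == drug &
    breakpoints$organism == suspected_pathogen
  if (!any(hit)) {
    stop("MIC unresolvable: no breakpoint for ", drug, " against ",
         suspected_pathogen,
         " (absent pairs include intrinsic resistance)", call. = FALSE)
  }
  structure(list(value = breakpoints$breakpoint_mg_L[which(hit)[1L]],
                 provenance = "breakpoint"),
            class = "effective_mic")
}

#' @export
print.effective_mic <- function(x, ...) {
  cat(sprintf("<effective_mic> %g mg/L [%s]\n", x$value, x$provenance))
  invisible(x)
}
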