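#' Default beta-lactam drug profiles
#'
#' Plasma protein binding for the eight beta-lactams quantified routinely by
#' the TDM service. The unbound (free) fraction is what penetrates to the
#' site of infection and drives the pharmacodynamic effect, so all target
#' attainment is computed on the free scale: free = total * fraction_unbound.
#'
#' Bound fractions are literature values: ampicillin 20%, aztreonam 56%,
#' cefazolin 80%, cefepime 20%, ceftriaxone 90%, meropenem 2%, oxacillin
#' 95%, piperacillin 30%. Drugs assayed only on request (e.g. amoxicillin,
#' imipenem, nafcillin) carry no default binding value and are deliberately
#' absent: passing them is a configuration error, not a silent fallback.
#'
#' @return A tibble with columns `drug`, `protein_bound`, `fraction_unbound`.
#' @export
#' @examples
#' drug_profiles()
drug_profiles <- function() {
  tibble::tibble(
    drug = c("ampicillin", "aztreonam", "cefazolin", "cefepime",
             "ceftriaxone", "meropenem", "oxacillin", "piperacillin"),
    protein_bound = c(0.20, 0.56, 0.80, 0.20, 0.90, 0.02, 0.95, 0.30)
  ) |>
    dplyr::mutate(fraction_unbound = 1 - protein_bound)
}

#' Unbound fraction for a drug
#'
#' @param drug Character vector of drug names.
#' @param profiles Drug profile table, as from [drug_profiles()].
#' @return Numeric vector of unbound fractions, same length as `drug`.
#' @export
fraction_unbound <- function(drug, profiles = drug_profiles()) {
  i <- match(drug, profiles$drug)
  if (anyNA(i)) {
    bad <- unique(drug[is.na(i)])
    stop("no protein-binding value configured for drug(s): ",
         paste(bad, collapse = ", "),
         ". Add them to the profile table explicitly.", call. = FALSE)
  }
  profiles$fraction_unbound[i]
}

#' Free (unbound) concentration from a total plasma concentration
#'
#' @param total Total plasma concentration(s), mg/L, >= 0.
#' @param drug Drug name(s), recycled against `total`.
#' @param profiles Drug profile table.
#' @return Free concentration(s), mg/L.
#' @export
#' @examples
#' free_concentration(10, "meropenem")   # 9.8
#' free_concentration(100, "ceftriaxone") # 10
free_concentration <- function(total, drug, profiles = drug_profiles()) {
  stopifnot(is.numeric(total))
  if (any(total < 0, na.rm = TRUE)) {
    stop("total concentration must be >= 0", call. = FALSE)
  }
  total * fraction_unbound(drug, profiles)
}

#' Default dose menus for regimen recommendation
#'
#' Candidate regimens searched when individualizing therapy, reflecting
#' label-style adult ICU dosing (doses in mg per administration, dosing
#' interval and infusion duration in hours). Continuous-infusion candidates
#' are represented over a 24 h reference window (`interval_h = infusion_h =
#' 24`, `dose_mg` = total daily dose). The menu is a configuration fixture,
#' not clinical advice.
#'
#' @param drug Optional drug name to filter on.
#' @return Tibble: `drug`, `dose_mg`, `interval_h`, `infusion_h`, `mode`.
#' @export
default_dose_menu <- function(drug = NULL) {
  grid <- function(d, doses, taus, tinfs) {
    g <- expand.grid(dose_mg = doses, interval_h = taus, infusion_h = tinfs,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[g$infusion_h < g$interval_h, , drop = FALSE]
    tibble::tibble(drug = d, g, mode = ifelse(g$infusion_h <= 1,
                                              "intermittent", "extended"))
  }
  cont <- function(d, daily) {
    tibble::tibble(drug = d, dose_mg = daily, interval_h = 24,
                   infusion_h = 24, mode = "continuous")
  }
  menu <- dplyr::bind_rows(
    grid("ampicillin",   c(1000, 2000), c(4, 6, 8),  c(0.5, 3)),
    grid("aztreonam",    c(1000, 2000), c(6, 8, 12), c(0.5, 3)),
    grid("cefazolin",    c(1000, 2000), c(6, 8, 12), c(0.5, 3)),
    grid("cefepime",     c(1000, 2000), c(6, 8, 12), c(0.5, 3)),
    cont("cefepime",     c(3000, 4000, 6000)),
    grid("ceftriaxone",  c(1000, 2000), c(12, 24),   c(0.5)),
    grid("meropenem",    c(500, 1000, 2000), c(6, 8, 12), c(0.5, 3)),
    cont("meropenem",    c(2000, 3000, 6000)),
    grid("oxacillin",    c(1000, 2000), c(4, 6),     c(0.5)),
    grid("piperacillin", c(3000, 4000), c(6, 8),     c(0.5, 4)),
    cont("piperacillin", c(12000, 16000))
  )
  if (!is.null(drug)) {
    menu <- menu[menu$drug == drug, , drop = FALSE]
    if (nrow(menu) == 0L) stop("no dose menu for drug: ", drug, call. = FALSE)
  }
  menu
}

#' Default empiric starting regimens
#'
#' Mid-menu standard regimens used as the pre-TDM prescription in the
#' synthetic cohort.
#'
#' @return Tibble with one row per drug: `drug`, `dose_mg`, `interval_h`,
#'   `infusion_h`, `mode`.
#' @export
default_empiric_regimens <- function() {
  tibble::tribble(
    ~drug,          ~dose_mg, ~interval_h, ~infusion_h,
    "ampicillin",   2000,     6,           0.5,
    "aztreonam",    2000,     8,           0.5,
    "cefazolin",    2000,     8,           0.5,
    "cefepime",     2000,     8,           0.5,
    "ceftriaxone",  2000,     24,          0.5,
    "meropenem",    1000,     8,           0.5,
    "oxacillin",    2000,     4,           0.5,
    "piperacillin", 4000,     8,           0.5
  ) |>
    dplyr::mutate(mode = "intermittent")
}
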