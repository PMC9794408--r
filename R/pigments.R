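# Chromophore quantification from extract absorbances: single-wavelength
# Beer-Lambert with native extinction coefficients, plus composition ratios.

#' Native extinction coefficients for the phycobilin chromophores
#'
#' Molar extinction coefficients (M^-1 cm^-1) and molar mass (g mol^-1,
#' identical for the three open-chain tetrapyrroles) used by default for
#' Beer-Lambert quantification: phycourobilin 105000, phycoerythrobilin
#' 136000, phycocyanobilin 102000; Mr 587 for all.
#'
#' @return Data frame with columns `chromophore`, `epsilon`, `mr`.
#' @export
extinction_defaults <- function() {
  data.frame(chromophore = c("PUB", "PEB", "PCB"),
             epsilon = c(105000, 136000, 102000),
             mr = c(587, 587, 587))
}

#' Beer-Lambert chromophore concentration
#'
#' `molar = A / (epsilon * path)`; mass concentration follows from the molar
#' mass. Optionally normalised per gram of tissue given the extraction
#' volume.
#'
#' @param absorbance extract absorbance (unitless), `>= 0`.
#' @param epsilon molar extinction coefficient (M^-1 cm^-1).
#' @param path_cm optical path length (cm), default 1.
#' @param mr molar mass (g mol^-1), default 587.
#' @param extraction_volume_mL,tissue_g optional extraction volume and tissue
#'   wet mass for per-gram normalisation.
#' @return List with `molar_M`, `micromolar`, `mg_per_L` and, when volume and
#'   tissue mass are supplied, `mg_per_g`.
#' @export
bilin_concentration <- function(absorbance, epsilon, path_cm = 1, mr = 587,
                                extraction_volume_mL = NULL, tissue_g = NULL) {
  if (any(absorbance < 0)) stop("absorbance must be >= 0", call. = FALSE)
  if (any(epsilon <= 0) || any(path_cm <= 0) || any(mr <= 0))
    stop("epsilon, path_cm and mr must be positive", call. = FALSE)
  molar <- absorbance / (epsilon * path_cm)
  out <- list(molar_M = molar,
              micromolar = molar * 1e6,
              mg_per_L = molar * mr * 1000)
  if (!is.null(extraction_volume_mL) && !is.null(tissue_g)) {
    if (any(tissue_g <= 0)) stop("tissue_g must be positive", call. = FALSE)
    out$mg_per_g <- out$mg_per_L * (extraction_volume_mL / 1000) / tissue_g
  }
  out
}

#' Linear-combination biliprotein quantification
#'
#' Spectrophotometric protocols express biliprotein concentrations as linear
#' combinations of absorbances at several wavelengths. The coefficient table
#' is supplied at runtime (rows = pigments, columns = wavelengths, in the
#' same units the coefficients were derived for), keeping the exact protocol
#' configurable.
#'
#' @param absorbances named numeric vector of absorbance readings; names are
#'   wavelengths, e.g. `c("565" = 0.8, "620" = 0.3)`.
#' @param coefficients numeric matrix with pigment row names and wavelength
#'   column names matching `absorbances`.
#' @return Named numeric vector of concentrations, one per coefficient row.
#' @export
biliprotein_concentrations <- function(absorbances, coefficients) {
  coefficients <- as.matrix(coefficients)
  if (is.null(colnames(coefficients)) || is.null(names(absorbances)))
    stop("absorbances and coefficient columns must be named by wavelength",
         call. = FALSE)
  miss <- setdiff(colnames(coefficients), names(absorbances))
  if (length(miss))
    stop("missing absorbance readings at: ", paste(miss, collapse = ", "),
         call. = FALSE)
  drop(coefficients %*% absorbances[colnames(coefficients)])
}

#' Pigment concentration panel
#'
#' Bundle of chromophore/biliprotein concentrations (one consistent unit,
#' e.g. mg/L or mg/g tissue). Missing members default to `NA`.
#'
#' @param chl_a,pe,pc,apc,pub,peb,pcb nonnegative concentrations.
#' @param units unit label carried along (default `"mg/L"`).
#' @return A list of class `pigment_panel`.
#' @export
pigment_panel <- function(chl_a = NA, pe = NA, pc = NA, apc = NA,
                          pub = NA, peb = NA, pcb = NA, units = "mg/L") {
  vals <- c(chl_a = chl_a, pe = pe, pc = pc, apc = apc,
            pub = pub, peb = peb, pcb = pcb)
  if (any(vals < 0, na.rm = TRUE))
    stop("concentrations must be >= 0", call. = FALSE)
  structure(c(as.list(vals), list(units = units)), class = "pigment_panel")
}

#' Chromophore composition as percentages
#'
#' Each member's share of the subset total, in percent; shares sum to 100.
#'
#' @param panel a [pigment_panel()].
#' @param members character vector of panel fields (default the three
#'   chromophores `pub`, `peb`, `pcb`).
#' @return Named numeric vector of percentages.
#' @export
composition_percent <- function(panel, members = c("peb", "pub", "pcb")) {
  stopifnot(inherits(panel, "pigment_panel"))
  vals <- unlist(panel[members])
  if (any(is.na(vals))) stop("panel members contain NA", call. = FALSE)
  tot <- sum(vals)
  if (tot <= 0)
    stop("undefined composition: subset total is zero", call. = FALSE)
  100 * vals / tot
}

#' Phycobilisome to chlorophyll-a concentration ratio
#'
#' `(PE + PC + APC) / chl_a` — total phycobilisome biliprotein over
#' chlorophyll-a.
#'
#' @param panel a [pigment_panel()] with `pe`, `pc`, `apc`, `chl_a`.
#' @return The PBS:Chl ratio.
#' @export
pbs_chl_ratio <- function(panel) {
  stopifnot(inherits(panel, "pigment_panel"))
  if (is.na(panel$chl_a) || panel$chl_a <= 0)
    stop("undefined ratio: chlorophyll-a concentration must be positive",
         call. = FALSE)
  (panel$pe + panel$pc + panel$apc) / panel$chl_a
}

#' Phycoerythrin to phycocyanin concentration ratio
#'
#' @param panel a [pigment_panel()] with `pe` and `pc`.
#' @return The PE:PC ratio.
#' @export
pe_pc_ratio <- function(panel) {
  stopifnot(inherits(panel, "pigment_panel"))
  if (is.na(panel$pc) || panel$pc <= 0)
    stop("undefined ratio: phycocyanin concentration must be positive",
         call. = FALSE)
  panel$pe / panel$pc
}
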