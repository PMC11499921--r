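#' Define a drug as a set of per-channel Hill parameters
#'
#' A drug is described by one row per blocked channel: the half-maximal
#' inhibitory concentration (IC50, in micromolar) and the Hill coefficient.
#' Channels without an entry are left unblocked.
#'
#' @param name Drug name.
#' @param channels A data frame with columns `channel`, `ic50_um`,
#'   `hill_coef` and optionally `source` (a citation string).
#' @return A `drug_spec` object (a tibble with attribute `name`).
#' @export
#' @examples
#' drug_spec("classIII", data.frame(channel = "IKr", ic50_um = 1, hill_coef = 1))
drug_spec <- function(name, channels) {
  channels <- as_tibble(channels)
  req <- c("channel", "ic50_um", "hill_coef")
  if (!all(req %in% names(channels)))
    abort(paste("drug_spec channels need columns:", paste(req, collapse = ", ")))
  bad <- setdiff(channels$channel, CHANNELS)
  if (length(bad) > 0)
    abort(paste("unknown channel(s):", paste(bad, collapse = ", ")))
  if (any(channels$ic50_um <= 0)) abort("ic50_um must be > 0")
  if (any(channels$hill_coef <= 0)) abort("hill_coef must be > 0")
  if (anyDuplicated(channels$channel)) abort("duplicate channel entries")
  if (!"source" %in% names(channels)) channels$source <- NA_character_
  structure(channels, class = c("drug_spec", class(channels)), name = name)
}

#' Default amiodarone blockade table
#'
#' Multichannel amiodarone profile assembled from patch-clamp literature
#' ranges: dominant rapid delayed-rectifier (IKr) block with accessory
#' sodium, L-type calcium, transient-outward and slow/ultrarapid potassium
#' block growing across the therapeutic range. The table is data, not
#' algorithm: replace any entry via [drug_spec()] or the drug table file.
#'
#' @return A `drug_spec`.
#' @export
amiodarone <- function() {
  drug_spec("amiodarone", tibble(
    channel   = c("INa", "ICaL", "Ito", "IKur", "IKr", "IKs", "IK1"),
    ic50_um   = c(12.0,  5.8,    10.0,  20.0,   1.2,   15.0,  40.0),
    hill_coef = c(1.0,   1.0,    1.0,   1.0,    0.9,   1.0,   1.0),
    source    = c("whole-cell INa block, mid-uM range",
                  "L-type Ca block, low-uM range",
                  "Ito block, mid-uM range",
                  "IKur block, weak",
                  "hERG/IKr block, ~1 uM",
                  "IKs block, mid-uM range",
                  "IK1 block, weak")))
}

#' Amiodarone dose presets
#'
#' The dosing grid used by the virtual drug test: none (0), low
#' (1.6 micromolar, minimal effective), high (3.9, maximal effective) and
#' toxic (8.0). `low` and `high` are the therapeutic doses.
#'
#' @return Tibble with columns `label`, `concentration_um`, `therapeutic`.
#' @export
dose_presets <- function() {
  tibble(label = c("none", "low", "high", "toxic"),
         concentration_um = c(0, 1.6, 3.9, 8.0),
         therapeutic = c(FALSE, TRUE, TRUE, FALSE))
}

#' Per-channel block fractions from the Hill equation
#'
#' Evaluates theta = 1 / (1 + (IC50 / D)^nH) for every channel of the model;
#' channels absent from the drug table get theta = 0. At D = 0 the
#' continuous limit theta = 0 is used.
#'
#' @param drug A [drug_spec()].
#' @param concentration_um Free drug concentration (micromolar), scalar >= 0.
#' @return Tibble with columns `channel` and `theta` (one row per channel,
#'   in model channel order).
#' @export
#' @examples
#' hill_blockade(amiodarone(), 1.6)
hill_blockade <- function(drug, concentration_um) {
  if (!inherits(drug, "drug_spec")) abort("`drug` must be a drug_spec")
  if (length(concentration_um) != 1 || !is.finite(concentration_um) ||
      concentration_um < 0)
    abort("`concentration_um` must be a single finite value >= 0")
  theta <- setNames(numeric(length(CHANNELS)), CHANNELS)
  if (concentration_um > 0) {
    th <- 1 / (1 + (drug$ic50_um / concentration_um)^drug$hill_coef)
    theta[drug$channel] <- th
  }
  tibble(channel = CHANNELS, theta = unname(theta))
}

#' Compose channel conductance scaling factors
#'
#' Builds the 13-channel multiplicative scaling vector applied to the cell
#' model: optional chronic-AF electrical remodeling, optional fibrotic-cell
#' current reductions (IK1 and ICaL halved, INa reduced by 40%), and an
#' optional drug blockade (each factor multiplied by 1 - theta). Factors
#' compose multiplicatively and 1 means unmodified.
#'
#' @param af_remodeling Apply the chronic-AF remodeling profile (default
#'   profile: ICaL x0.3, Ito x0.5, IKur x0.5, IK1 x2.0; replaceable via
#'   `remodeling`).
#' @param fibrotic Apply the fibrotic-cell profile (IK1 x0.5, ICaL x0.5,
#'   INa x0.6).
#' @param blockade Optional blockade tibble from [hill_blockade()].
#' @param remodeling Optional named vector overriding the AF-remodeling
#'   profile.
#' @return Named numeric vector of length 13, class `conductance_scaling`.
#' @export
conductance_scaling <- function(af_remodeling = FALSE, fibrotic = FALSE,
                                blockade = NULL, remodeling = NULL) {
  g <- setNames(rep(1, length(CHANNELS)), CHANNELS)
  if (af_remodeling) {
    prof <- remodeling %||% af_remodeling_profile()
    g[names(prof)] <- g[names(prof)] * prof
  }
  if (fibrotic) {
    prof <- fibrosis_profile()
    g[names(prof)] <- g[names(prof)] * prof
  }
  g <- structure(g, class = "conductance_scaling")
  if (!is.null(blockade)) g <- apply_drug(g, blockade)
  g
}

#' Chronic-AF remodeling profile (conductance multipliers)
#'
#' Default ion-channel remodeling applied to every myocyte of an AF
#' substrate: reduced L-type calcium, transient-outward and ultrarapid
#' potassium conductances with increased inward rectifier. Standard
#' chronic-AF remodeling for this model family; user-replaceable.
#'
#' @return Named numeric vector.
#' @export
af_remodeling_profile <- function() {
  c(ICaL = 0.3, Ito = 0.5, IKur = 0.5, IK1 = 2.0)
}

#' Fibrotic-myocyte current reductions
#'
#' IK1 and ICaL reduced by 50% and INa by 40% in cells flagged fibrotic.
#'
#' @return Named numeric vector.
#' @export
fibrosis_profile <- function() {
  c(IK1 = 0.5, ICaL = 0.5, INa = 0.6)
}

#' Apply a drug blockade to a conductance scaling
#'
#' Each channel factor is multiplied by (1 - theta). Composition with other
#' scaling sources is order-independent.
#'
#' @param scaling A `conductance_scaling` (or named numeric vector).
#' @param blockade Tibble with `channel`, `theta` from [hill_blockade()].
#' @return Updated `conductance_scaling`.
#' @export
apply_drug <- function(scaling, blockade) {
  if (!all(c("channel", "theta") %in% names(blockade)))
    abort("`blockade` needs columns channel, theta")
  if (any(!is.finite(blockade$theta)) || any(blockade$theta < 0) ||
      any(blockade$theta > 1))
    abort("theta values must lie in [0, 1]")
  th <- setNames(blockade$theta, blockade$channel)
  out <- unclass(scaling)
  out[names(th)] <- out[names(th)] * (1 - th)
  structure(out, class = "conductance_scaling")
}

as_scaling_vector <- function(scaling) {
  if (inherits(scaling, "conductance_scaling") ||
      (is.numeric(scaling) && !is.null(names(scaling)))) {
    v <- unclass(scaling)
    if (!all(CHANNELS %in% names(v))) abort("scaling must name all 13 channels")
    if (any(!is.finite(v)) || any(v < 0)) abort("scaling factors must be finite and >= 0")
    return(unname(v[CHANNELS]))
  }
  abort("scaling must be a conductance_scaling or a named numeric vector")
}
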