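#' Saturating compression of abundance to bound fraction
#'
#' Maps an effective reaction abundance `a` into a fraction of the maximal
#' flux bound via a Michaelis-Menten-like curve rescaled to pass through 1
#' at the most abundant reaction:
#'
#' \deqn{\hat s(a) = \frac{a (1 + k)}{a + k\,a_{max}}}
#'
#' `k` is the dimensionless half-saturation fraction ("compression"): as
#' `k` grows the mapping approaches the linear `a / a_max`; as `k` shrinks
#' toward 0 every expressed enzyme approaches the full bound, so weakly
#' expressed enzymes stop being limiting. In either limit
#' `compress(a_max) == 1`, which keeps the bound of the most abundant
#' reaction fixed at `b_max` across the compression sweep.
#'
#' @param a abundance(s), `0 <= a <= a_max`.
#' @param a_max abundance of the most abundant reaction (> 0).
#' @param k compression parameter (> 0).
#' @return fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' compress_abundance(5, 10, k = 1) # 2/3
compress_abundance <- function(a, a_max, k) {
  stopifnot(k > 0)
  if (!is.finite(a_max) || a_max <= 0) stop("a_max must be positive")
  if (any(a < 0 | a > a_max + 1e-9 * a_max, na.rm = TRUE)) {
    stop("abundances must lie in [0, a_max]")
  }
  ifelse(a == 0, 0, a * (1 + k) / (a + k * a_max))
}

#' Constrain internal reactions by enzyme abundance
#'
#' For every gene-associated reaction the upper bound becomes
#' `b_max * compress_abundance(effective, max(effective), k)`; the lower
#' bound becomes the negative of that for reversible reactions (original
#' `lb < 0`) and stays 0 for irreversible ones. Reactions without a
#' gene-reaction rule keep the model's default bounds. Exchange reactions
#' are never touched here (see [exchange_bounds()]).
#'
#' @param model a [metabolic_model()].
#' @param effective tibble from [reaction_abundance()], or a named numeric
#'   vector reaction id -> effective abundance.
#' @param k compression parameter.
#' @param b_max flux bound assigned to the most abundant reaction.
#' @return model with updated internal bounds.
#' @export
internal_bounds <- function(model, effective, k, b_max = 1000) {
  stopifnot(inherits(model, "metabolic_model"), b_max > 0)
  if (is.data.frame(effective)) {
    effective <- stats::setNames(effective$effective, effective$reaction_id)
  }
  keep <- !is.na(effective)
  effective <- effective[keep]
  idx <- match(names(effective), model$reactions$id)
  if (anyNA(idx)) stop("effective abundances cite unknown reactions")
  idx_ok <- !model$reactions$exchange[idx]
  idx <- idx[idx_ok]
  effective <- effective[idx_ok]
  if (length(effective) == 0) return(model)
  a_max <- max(effective)
  if (a_max <= 0) {
    s <- rep(0, length(effective))
  } else {
    s <- compress_abundance(effective, a_max, k)
  }
  reversible <- model$reactions$lb[idx] < 0
  model$reactions$ub[idx] <- b_max * s
  model$reactions$lb[idx] <- ifelse(reversible, -b_max * s, 0)
  model
}

#' Exchange-flux specification
#'
#' Bundles everything needed to set exchange-reaction lower bounds: the
#' growth-medium composition for availability-proportional ("dmem") bounds,
#' and optionally measured uptake/secretion fluxes for the "measured"
#' (real-world) mode.
#'
#' @param mode `"dmem"` (medium-proportional) or `"measured"`.
#' @param medium tibble with `metabolite_id`, `mM`; must contain glucose.
#' @param measured_fluxes tibble with `metabolite_id`, `flux` (signed,
#'   uptake negative) for one condition; required in measured mode and must
#'   include glucose.
#' @param r availability ratio: magnitude of the reference (glucose)
#'   exchange bound relative to `b_max` (>= 0).
#' @param glucose_id metabolite id of glucose in the model/medium.
#' @param efflux_policy in measured mode, whether a measured secretion sets
#'   a floor on efflux (`"floor"`, lower bound at the measured value) or
#'   leaves the bound free (`"free"`).
#' @return list of class `exchange_spec`.
#' @export
exchange_spec <- function(mode = c("dmem", "measured"),
                          medium,
                          measured_fluxes = NULL,
                          r = 0.05,
                          glucose_id = "glc_e",
                          efflux_policy = c("floor", "free")) {
  mode <- match.arg(mode)
  efflux_policy <- match.arg(efflux_policy)
  stopifnot(r >= 0, is.data.frame(medium),
            all(c("metabolite_id", "mM") %in% names(medium)))
  if (!glucose_id %in% medium$metabolite_id) {
    stop("medium must contain glucose ('", glucose_id, "')")
  }
  if (mode == "measured") {
    if (is.null(measured_fluxes) ||
        !glucose_id %in% measured_fluxes$metabolite_id) {
      stop("measured mode requires measured fluxes including glucose")
    }
  }
  structure(list(mode = mode, medium = tibble::as_tibble(medium),
                 measured_fluxes = if (!is.null(measured_fluxes))
                   tibble::as_tibble(measured_fluxes),
                 r = r, glucose_id = glucose_id,
                 efflux_policy = efflux_policy),
            class = "exchange_spec")
}

#' Rescale measured exchange fluxes to the model's glucose reference
#'
#' Measured exchange rates are put on the model's availability scale by one
#' multiplicative factor per condition chosen so the glucose flux equals
#' `-reference` (default 25, the glucose concentration of DMEM in mM, which
#' anchors the medium-proportional scale). Signs are preserved, so secreted
#' metabolites stay positive.
#'
#' @param measured tibble with `metabolite_id`, `flux` (uptake negative).
#' @param glucose_id glucose metabolite id.
#' @param reference magnitude the glucose flux is scaled to.
#' @return tibble with columns `metabolite_id`, `flux` (rescaled), plus a
#'   `scale` attribute holding the factor applied.
#' @export
normalize_measured_fluxes <- function(measured, glucose_id = "glc_e",
                                      reference = 25) {
  stopifnot(is.data.frame(measured),
            all(c("metabolite_id", "flux") %in% names(measured)))
  glc <- measured$flux[measured$metabolite_id == glucose_id]
  if (length(glc) != 1 || is.na(glc) || glc >= 0) {
    stop("measured fluxes must contain a single negative glucose uptake")
  }
  fac <- reference / abs(glc)
  out <- dplyr::mutate(tibble::as_tibble(measured), flux = .data$flux * fac)
  attr(out, "scale") <- fac
  out
}

#' Set exchange-reaction bounds from medium or measured fluxes
#'
#' In `"dmem"` mode every exchange metabolite present in the medium gets an
#' uptake lower bound proportional to its concentration relative to
#' glucose: `lb = -r * b_max * mM / mM_glucose`; metabolites absent from
#' the medium get uptake bound 0 (secretion stays allowed). Oxygen, water
#' and protons are treated as freely available unless listed in the medium.
#'
#' In `"measured"` mode the measured fluxes are first rescaled with
#' [normalize_measured_fluxes()] (glucose to -25 on the medium scale), then
#' converted to model flux units by `r * b_max / 25`. Measured uptakes set
#' the exchange lower bound; measured secretions set a floor on efflux (or
#' are left free, per `efflux_policy`). Unmeasured exchanges keep their
#' medium-proportional bounds.
#'
#' @param model a [metabolic_model()].
#' @param spec an [exchange_spec()].
#' @param b_max flux bound of the most abundant internal reaction (sets the
#'   overall scale).
#' @param free_metabolites metabolite ids whose uptake is never restricted
#'   (default oxygen).
#' @return model with updated exchange bounds.
#' @export
exchange_bounds <- function(model, spec, b_max = 1000,
                            free_metabolites = c("o2_e")) {
  stopifnot(inherits(model, "metabolic_model"), inherits(spec, "exchange_spec"))
  medium <- spec$medium
  glc_mM <- medium$mM[medium$metabolite_id == spec$glucose_id]
  ex_ids <- model$reactions$id[model$reactions$exchange]
  st <- model$stoichiometry
  unit <- spec$r * b_max / glc_mM   # flux units per mM on the medium scale

  measured <- NULL
  if (spec$mode == "measured") {
    measured <- normalize_measured_fluxes(spec$measured_fluxes,
                                          glucose_id = spec$glucose_id,
                                          reference = glc_mM)
  }

  for (rid in ex_ids) {
    met <- st$metabolite_id[st$reaction_id == rid][1]
    if (met %in% free_metabolites) next
    meas <- if (!is.null(measured)) {
      measured$flux[measured$metabolite_id == met]
    } else numeric()
    if (length(meas) == 1) {
      v <- meas * unit
      if (v < 0) {
        model <- set_bounds(model, rid, lb = v)
      } else if (spec$efflux_policy == "floor") {
        model <- set_bounds(model, rid, lb = v)
      }
      next
    }
    mM <- medium$mM[medium$metabolite_id == met]
    lb <- if (length(mM) == 1) -unit * mM else 0
    model <- set_bounds(model, rid, lb = lb)
  }
  model
}
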