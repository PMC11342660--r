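#' Calibrate a Gamma decay specification to a target median lifetime
#'
#' Product-pool decay follows a Gamma survival curve
#' `S(t) = 1 - F(t; shape, scale)`: unlike exponential decay it produces a
#' lag after product creation before losses peak. The scale is solved so
#' that the cumulative distribution at `median_years` equals 0.5, i.e. half
#' of a vintage has decayed by its median lifetime (3 / 18 / 93 years for
#' the short-, medium- and long-lived pools).
#'
#' @param pool_class one of `"short"`, `"medium"`, `"long"`.
#' @param median_years target median lifetime, years (> 0).
#' @param shape Gamma shape parameter (> 0; default 2).
#' @return list of class `decay_spec` with `pool_class`, `median_years`,
#'   `shape`, `scale`.
#' @export
#' @examples
#' sp <- gamma_decay_spec("long", 93)
#' product_survival(sp, 93)  # 0.5
gamma_decay_spec <- function(pool_class = c("short", "medium", "long"),
                             median_years, shape = 2) {
  pool_class <- match.arg(pool_class)
  if (median_years <= 0 || shape <= 0)
    stop("median_years and shape must be positive")
  scale <- median_years / stats::qgamma(0.5, shape = shape)
  err <- stats::pgamma(median_years, shape = shape, scale = scale) - 0.5
  if (!is.finite(scale) || abs(err) > 1e-8)
    stop(sprintf("gamma calibration failed: median=%g shape=%g scale=%g residual=%g",
                 median_years, shape, scale, err))
  structure(list(pool_class = pool_class, median_years = median_years,
                 shape = shape, scale = scale),
            class = "decay_spec")
}

#' Survival fraction of a product vintage at a given age
#'
#' @param spec a [gamma_decay_spec()] object.
#' @param t age since product creation, years (vectorized); negative ages
#'   survive fully.
#' @return fraction of the vintage's carbon still in use.
#' @export
product_survival <- function(spec, t) {
  ifelse(t <= 0, 1,
         1 - stats::pgamma(t, shape = spec$shape, scale = spec$scale))
}

#' Default decay specifications for the three product pools
#'
#' @param shape Gamma shape parameter applied to all pools.
#' @return named list of `decay_spec` (`short`, `medium`, `long`) with
#'   median lifetimes 3, 18 and 93 years.
#' @export
default_decay_specs <- function(shape = 2) {
  list(short  = gamma_decay_spec("short",  3,  shape),
       medium = gamma_decay_spec("medium", 18, shape),
       long   = gamma_decay_spec("long",   93, shape))
}

#' Extend product residence times (cascade usage)
#'
#' Models increased cascading (re-use, recycling) by increasing the Gamma
#' shape parameter — the scale is held fixed — until the median lifetime
#' equals `factor` times the original median. Applied downstream only to
#' products created after 2020.
#'
#' @param spec a [gamma_decay_spec()] object.
#' @param factor median-lifetime multiplier (>= 1).
#' @return a recalibrated `decay_spec` (unchanged if `factor == 1`).
#' @export
#' @examples
#' apply_cascading(gamma_decay_spec("long", 93), 1.5)$median_years  # 139.5
apply_cascading <- function(spec, factor) {
  if (factor < 1) stop("cascade factor must be >= 1")
  if (factor == 1) return(spec)
  target <- factor * spec$median_years
  f <- function(sh) stats::qgamma(0.5, shape = sh) * spec$scale - target
  sol <- tryCatch(
    stats::uniroot(f, lower = spec$shape, upper = spec$shape * 20,
                   extendInt = "upX", tol = 1e-12),
    error = function(e)
      stop(sprintf("cascading shape solve failed (median=%g factor=%g): %s",
                   spec$median_years, factor, conditionMessage(e))))
  out <- spec
  out$shape <- sol$root
  out$median_years <- target
  err <- stats::pgamma(target, shape = out$shape, scale = out$scale) - 0.5
  if (abs(err) > 1e-6)
    stop(sprintf("cascading verification failed: residual %g", err))
  out
}

#' Allocation fractions of removed stem wood to product classes
#'
#' Baseline shares of removed stem carbon entering the long-, medium- and
#' short-lived product pools — needle-leaved: 37% / 17% / 36%,
#' broad-leaved: 6% / 34% / 25% — with the remainder burned as fuel wood in
#' the harvest year. Under the increased-material-usage scenario the long
#' and medium shares are scaled by `1 + (material_usage - 1) * ramp`, with a
#' linear ramp from 2020 to 2050, at the expense of the short-lived and
#' fuel shares, which are reduced in proportion to their baseline sizes.
#' The four fractions always sum to exactly 1.
#'
#' @param forest_type `"NE"` or `"BD"`.
#' @param year calendar year.
#' @param material_usage usage multiplier (1 = baseline, 1.5 = +50% by 2050).
#' @return named numeric vector `c(long, medium, short, fuel)`.
#' @export
#' @examples
#' usage_fractions("NE", 2050, 1.5)[["long"]]  # 0.555
usage_fractions <- function(forest_type, year, material_usage = 1) {
  base <- switch(as.character(forest_type),
    NE = c(long = 0.37, medium = 0.17, short = 0.36, fuel = 0.10),
    BD = c(long = 0.06, medium = 0.34, short = 0.25, fuel = 0.35),
    stop_config("unknown forest type: ", forest_type))
  if (material_usage == 1) return(base)
  ramp <- clamp((year - 2020) / 30, 0, 1)
  boost <- 1 + (material_usage - 1) * ramp
  long <- base[["long"]] * boost
  medium <- base[["medium"]] * boost
  deficit <- (long + medium) - (base[["long"]] + base[["medium"]])
  pool <- base[["short"]] + base[["fuel"]]
  if (deficit > pool)
    stop_config("material usage multiplier ", material_usage,
                " drives short/fuel fractions negative in ", year)
  short <- base[["short"]] - deficit * base[["short"]] / pool
  fuel <- 1 - long - medium - short
  c(long = long, medium = medium, short = short, fuel = fuel)
}

# ---- explicit vintage ledger --------------------------------------------

#' Create an empty wood-product ledger
#'
#' A vintage-resolved record of product carbon: each cohort is one
#' (vintage year, pool class) parcel with its own decay specification.
#' The ledger is the reference implementation of product decay; the
#' vectorized [product_dynamics()] pipeline must agree with it.
#'
#' @return object of class `product_ledger`.
#' @export
product_ledger <- function() {
  structure(list(cohorts = data.frame(vintage = integer(), class = character(),
                                      initial = numeric(), shape = numeric(),
                                      scale = numeric())),
            class = "product_ledger")
}

#' Add a product vintage to a ledger
#'
#' @param ledger a [product_ledger()].
#' @param year vintage (creation) year.
#' @param inflows named numeric vector of carbon by pool class (kgC/m2),
#'   names among `"short"`, `"medium"`, `"long"`.
#' @param specs named list of `decay_spec` per class (post-cascading if the
#'   vintage falls under a cascade scenario).
#' @return the updated ledger.
#' @export
ledger_add <- function(ledger, year, inflows, specs = default_decay_specs()) {
  if (any(inflows < 0)) stop("product inflows must be nonnegative")
  keep <- names(inflows)[inflows > 0]
  for (cl in keep) {
    sp <- specs[[cl]]
    ledger$cohorts <- rbind(ledger$cohorts, data.frame(
      vintage = year, class = cl, initial = inflows[[cl]],
      shape = sp$shape, scale = sp$scale))
  }
  ledger
}

ledger_survival <- function(cohorts, age) {
  ifelse(age <= 0, 1,
         1 - stats::pgamma(age, shape = cohorts$shape, scale = cohorts$scale))
}

#' Decay a product ledger over one year
#'
#' Each cohort of age `a = year - vintage` loses
#' `initial * (S(a - 1) - S(a))` during `year`; age-0 cohorts do not decay
#' in their creation year (survival starts at 1). Decayed carbon is emitted
#' to the atmosphere and is available for end-of-life energy recovery.
#'
#' @param ledger a [product_ledger()].
#' @param year calendar year being decayed.
#' @return named numeric vector of decayed carbon by pool class (kgC/m2),
#'   with an attribute `total`.
#' @export
ledger_step <- function(ledger, year) {
  out <- c(short = 0, medium = 0, long = 0)
  ch <- ledger$cohorts
  if (nrow(ch)) {
    age <- year - ch$vintage
    dec <- ch$initial * (ledger_survival(ch, age - 1) - ledger_survival(ch, age))
    dec[age <= 0] <- 0
    for (cl in names(out)) out[[cl]] <- sum(dec[ch$class == cl])
  }
  attr(out, "total") <- sum(out)
  out
}

#' Remaining carbon in a product ledger
#'
#' Vintages with a creation year after the evaluation year do not
#' contribute (they do not exist yet).
#'
#' @param ledger a [product_ledger()].
#' @param year evaluation year (end of year).
#' @return total remaining product carbon, kgC/m2.
#' @export
ledger_total <- function(ledger, year) {
  ch <- ledger$cohorts[ledger$cohorts$vintage <= year, , drop = FALSE]
  if (!nrow(ch)) return(0)
  sum(ch$initial * ledger_survival(ch, year - ch$vintage))
}

# ---- vectorized product + substitution pipeline -------------------------

#' Product pools, decay and substitution credits for a harvest series
#'
#' Takes the annual removed-stem and firewood fluxes of a simulated stand
#' and layers the wood-product stage on top: allocation to the three
#' product pools via [usage_fractions()] (the fuel share burns in the
#' harvest year), Gamma-survival decay per vintage (with cascading applied
#' to vintages after 2020), and the three substitution-credit streams —
#' material credit at product creation, fuel credit for all combustion
#' (stand firewood plus the stem fuel share), and end-of-life credit for
#' decayed products under full energy recovery — each scaled by the
#' decarbonization multiplier of its booking year.
#'
#' @param removed_stem annual removed stem carbon, kgC/m2/yr.
#' @param firewood annual firewood carbon burned at the stand
#'   (young trees, branches), kgC/m2/yr.
#' @param years calendar years (same length as the flux vectors).
#' @param forest_type `"NE"` or `"BD"` (sets the allocation baseline).
#' @param material_usage usage multiplier (1 or 1.5).
#' @param cascade cascade multiplier for vintages after `cascade_from`.
#' @param decarb_2050 decarbonization pace (DF fraction remaining in 2050).
#' @param specs decay specifications, [default_decay_specs()].
#' @param subst a [substitution_params()] object.
#' @param cascade_from vintages strictly after this year are cascaded.
#' @return `data.frame` of class `product_series`: `year`, pools
#'   `product_short_c`, `product_medium_c`, `product_long_c` (kgC/m2),
#'   fluxes `product_inflow`, `product_decay`, `stem_fuel` (kgC/m2/yr) and
#'   credits `avoided_material`, `avoided_fuel`, `avoided_eol` (kgC/m2/yr).
#' @export
product_dynamics <- function(removed_stem, firewood, years, forest_type,
                             material_usage = 1, cascade = 1,
                             decarb_2050 = 0.5,
                             specs = default_decay_specs(),
                             subst = substitution_params(),
                             cascade_from = 2020) {
  ny <- length(years)
  stopifnot(length(removed_stem) == ny, length(firewood) == ny)
  classes <- c("long", "medium", "short")
  fr <- vapply(years, function(y)
    usage_fractions(forest_type, y, material_usage), numeric(4))
  inflow <- t(fr[classes, , drop = FALSE]) * removed_stem   # ny x 3
  stem_fuel <- fr["fuel", ] * removed_stem

  ages <- 0:(ny - 1)
  pool <- matrix(0, ny, 3, dimnames = list(NULL, classes))
  decay <- matrix(0, ny, 3, dimnames = list(NULL, classes))
  for (cl in classes) {
    S_pre <- product_survival(specs[[cl]], ages)
    S_post <- if (cascade > 1)
      product_survival(apply_cascading(specs[[cl]], cascade), ages)
    else S_pre
    D_pre <- c(0, -diff(S_pre))
    D_post <- c(0, -diff(S_post))
    for (j in seq_len(ny)) {
      x <- inflow[j, cl]
      if (x == 0) next
      cascaded <- cascade > 1 && years[j] > cascade_from
      S <- if (cascaded) S_post else S_pre
      D <- if (cascaded) D_post else D_pre
      idx <- j:ny
      rel <- seq_along(idx)
      pool[idx, cl] <- pool[idx, cl] + x * S[rel]
      decay[idx, cl] <- decay[idx, cl] + x * D[rel]
    }
  }

  m <- decarb_multiplier(years, decarb_2050)
  avoided_material <- subst$df_material * m * rowSums(inflow)
  avoided_fuel <- subst$df_fuel * m * (firewood + stem_fuel)
  avoided_eol <- subst$df_fuel * m * rowSums(decay)

  out <- data.frame(year = years,
                    product_short_c = pool[, "short"],
                    product_medium_c = pool[, "medium"],
                    product_long_c = pool[, "long"],
                    product_inflow = rowSums(inflow),
                    product_decay = rowSums(decay),
                    stem_fuel = stem_fuel,
                    avoided_material = avoided_material,
                    avoided_fuel = avoided_fuel,
                    avoided_eol = avoided_eol)
  attr(out, "settings") <- list(forest_type = forest_type,
                                material_usage = material_usage,
                                cascade = cascade,
                                decarb_2050 = decarb_2050)
  class(out) <- c("product_series", "data.frame")
  out
}
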