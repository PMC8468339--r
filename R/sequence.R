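#' Contrast parameters of one pulse sequence
#'
#' Vendor-neutral parameter set for the supported steady-state families:
#' spin echo (`SE`), fast spin echo (`FSE`), spoiled gradient echo
#' (`GRE_SPOILED`) and inversion-recovery spin echo (`IR_SE`). All times in
#' milliseconds, flip angle in degrees.
#'
#' @param family sequence family.
#' @param te echo time, ms (>= 0).
#' @param tr repetition time, ms (> te).
#' @param ti inversion time, ms (IR_SE only, `0 < ti < tr`).
#' @param flip_deg excitation flip angle, degrees (GRE_SPOILED only, in
#'   (0, 90]).
#' @param etl echo train length (FSE only, >= 1).
#' @param echo_spacing inter-echo spacing, ms (FSE only, > 0).
#' @param shimming_on when `TRUE` the field-inhomogeneity map is treated as
#'   perfectly corrected (dB0 = 0) during contrast evaluation.
#' @param field_strength_t main field strength in tesla; scales the
#'   dB0-induced T2* shortening only (relaxation times are deliberately not
#'   rescaled with field).
#' @return an object of class `sequence_params`.
#' @export
sequence_params <- function(family, te, tr, ti = NULL, flip_deg = NULL,
                            etl = NULL, echo_spacing = NULL,
                            shimming_on = FALSE, field_strength_t = 1.5) {
  family <- match.arg(family, c("SE", "FSE", "GRE_SPOILED", "IR_SE"))
  stopifnot_scalar(te, "te", 0)
  stopifnot_scalar(tr, "tr", 0, strict_lower = TRUE)
  if (tr <= te) abort_invalid(sprintf("tr (%g) must exceed te (%g)", tr, te))
  if (family == "IR_SE") {
    if (is.null(ti)) abort_invalid("family IR_SE requires parameter 'ti'")
    stopifnot_scalar(ti, "ti", 0, strict_lower = TRUE)
    if (ti >= tr) abort_invalid(sprintf("ti (%g) must be < tr (%g)", ti, tr))
  }
  if (family == "GRE_SPOILED") {
    if (is.null(flip_deg)) abort_invalid("family GRE_SPOILED requires 'flip_deg'")
    if (!is_scalar_number(flip_deg) || flip_deg <= 0 || flip_deg > 90)
      abort_invalid("flip_deg must lie in (0, 90]")
  }
  if (family == "FSE") {
    if (is.null(etl)) etl <- 1L
    etl <- as.integer(etl)
    if (etl < 1L) abort_invalid("etl must be >= 1")
    if (is.null(echo_spacing)) echo_spacing <- max(te, 1)
    stopifnot_scalar(echo_spacing, "echo_spacing", 0, strict_lower = TRUE)
  }
  stopifnot_scalar(field_strength_t, "field_strength_t", 0, strict_lower = TRUE)
  structure(list(family = family, te = te, tr = tr, ti = ti,
                 flip_deg = flip_deg, etl = etl, echo_spacing = echo_spacing,
                 shimming_on = isTRUE(shimming_on),
                 field_strength_t = field_strength_t),
            class = "sequence_params")
}

#' @export
print.sequence_params <- function(x, ...) {
  extra <- switch(x$family,
    IR_SE = sprintf(", TI %g ms", x$ti),
    GRE_SPOILED = sprintf(", flip %g deg", x$flip_deg),
    FSE = sprintf(", ETL %d, echo spacing %g ms", x$etl, x$echo_spacing),
    "")
  cat(sprintf("sequence_params: %s, TE %g ms, TR %g ms%s, %g T%s\n",
              x$family, x$te, x$tr, extra, x$field_strength_t,
              if (x$shimming_on) ", shimmed" else ""))
  invisible(x)
}

#' Spin-echo steady-state signal
#'
#' Canonical saturation-recovery spin-echo expression
#' `S = pd * (1 - exp(-tr/t1)) * exp(-te/t2)`. All arguments vectorise.
#'
#' @param pd proton density in \[0, 1\].
#' @param t1,t2 relaxation times, ms (> 0).
#' @param te,tr echo / repetition times, ms.
#' @return dimensionless signal in `[0, pd]`.
#' @export
#' @examples
#' signal_se(pd = 0.8, t1 = 1000, t2 = 80, te = 20, tr = 500)
signal_se <- function(pd, t1, t2, te, tr) {
  if (any(t1 <= 0) || any(t2 <= 0))
    abort_invalid("t1 and t2 must be positive", class = "mrisim_domain_error")
  if (any(te < 0) || any(tr <= 0)) abort_invalid("te must be >= 0 and tr > 0")
  pd * (1 - exp(-tr / t1)) * exp(-te / t2)
}

#' Spoiled gradient-echo steady-state signal
#'
#' `S = pd * sin(a) * (1 - E1) / (1 - cos(a) * E1) * exp(-te/t2star)` with
#' `E1 = exp(-tr/t1)`. The T2* argument (not T2) carries the
#' field-inhomogeneity sensitivity of gradient echoes; see [t2star_map()].
#'
#' @inheritParams signal_se
#' @param t2star effective transverse relaxation time, ms.
#' @param flip_deg flip angle in degrees, in (0, 90].
#' @export
#' @examples
#' ernst <- acos(exp(-500 / 1000)) * 180 / pi
#' signal_gre_spoiled(1, 1000, 80, te = 0, tr = 500, flip_deg = ernst)
signal_gre_spoiled <- function(pd, t1, t2star, te, tr, flip_deg) {
  if (any(t1 <= 0) || any(t2star <= 0))
    abort_invalid("t1 and t2star must be positive", class = "mrisim_domain_error")
  if (any(flip_deg <= 0) || any(flip_deg > 90))
    abort_invalid("flip_deg must lie in (0, 90]")
  a <- flip_deg * pi / 180
  e1 <- exp(-tr / t1)
  pd * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-te / t2star)
}

#' Inversion-recovery spin-echo signal (magnitude reconstruction)
#'
#' `S = pd * |1 - 2 exp(-ti/t1) + exp(-tr/t1)| * exp(-te/t2)`; the absolute
#' value reflects magnitude reconstruction, so a tissue is nulled when
#' `ti = t1 * log(2)` (for long TR).
#'
#' @inheritParams signal_se
#' @param ti inversion time, ms (must satisfy `ti < tr`).
#' @export
#' @examples
#' signal_ir(1, t1 = 800, t2 = 80, te = 0, tr = 3000, ti = 400)
signal_ir <- function(pd, t1, t2, te, tr, ti) {
  if (any(t1 <= 0) || any(t2 <= 0))
    abort_invalid("t1 and t2 must be positive", class = "mrisim_domain_error")
  if (any(ti >= tr)) abort_invalid("ti must be < tr")
  if (any(ti <= 0)) abort_invalid("ti must be > 0")
  pd * abs(1 - 2 * exp(-ti / t1) + exp(-tr / t1)) * exp(-te / t2)
}

#' Gyromagnetic dephasing constant
#'
#' Rate constant translating a field offset into additional transverse
#' relaxation: `gamma_prime = 2 * pi * 42.576 MHz/T * 1e-6 / 1000`
#' = 0.2675 (ms^-1) per (tesla * ppm), i.e. the angular off-resonance
#' frequency of a 1 ppm offset at 1 T expressed per millisecond.
#' @keywords internal
GAMMA_PRIME_MS_T_PPM <- 2 * pi * 42.576 * 1e-3  # 1/(ms * T * ppm)

#' Effective T2* map from T2 and a field-offset map
#'
#' Adopts the standard additive-rate model
#' `1/t2star = 1/t2 + gamma_prime * B0 * |dB0_ppm|` with `gamma_prime`
#' fixed at `0.2675 / (ms * T * ppm)` (the angular frequency of a 1 ppm
#' offset). A zero field map returns T2 exactly, which is also what the
#' shimming option enforces.
#'
#' @param t2 T2 values, ms (matrix or vector).
#' @param delta_b0 field offset in ppm (same shape).
#' @param field_strength_t main field, tesla.
#' @return T2* in ms, same shape as `t2`.
#' @export
t2star_map <- function(t2, delta_b0, field_strength_t = 1.5) {
  if (any(t2 <= 0)) abort_invalid("t2 must be positive",
                                  class = "mrisim_domain_error")
  1 / (1 / t2 + GAMMA_PRIME_MS_T_PPM * field_strength_t * abs(delta_b0))
}

#' Saturation band definition
#'
#' A planar slab inside which longitudinal magnetisation is suppressed
#' before acquisition. The suppression factor multiplies proton density, so
#' its effect propagates identically through every sequence family.
#'
#' @param centre slab centre, world mm.
#' @param normal slab normal (normalised internally).
#' @param thickness slab thickness, mm (> 0).
#' @param suppression residual signal factor in \[0, 1\] (0 = complete
#'   suppression).
#' @return an object of class `saturation_band`.
#' @export
saturation_band <- function(centre, normal, thickness, suppression = 0) {
  stopifnot_scalar(thickness, "thickness", 0, strict_lower = TRUE)
  stopifnot_scalar(suppression, "suppression", 0, 1)
  n <- as.numeric(normal)
  if (length(n) != 3L || sum(n^2) == 0) abort_invalid("normal must be a nonzero 3-vector")
  structure(list(centre = as.numeric(centre), normal = n / sqrt(sum(n^2)),
                 thickness = thickness, suppression = suppression),
            class = "saturation_band")
}

#' Receive-coil sensitivity profile
#'
#' Two pedagogically distinct models: a homogeneous (body) coil with unit
#' sensitivity everywhere, and a surface coil whose sensitivity falls off as
#' `exp(-distance / falloff)` with Euclidean distance from the coil
#' reference point.
#'
#' @param kind `"homogeneous"` or `"surface"`.
#' @param reference coil reference point, world mm (surface only).
#' @param falloff e-folding length, mm (surface only, > 0).
#' @return an object of class `coil_profile`.
#' @export
coil_profile <- function(kind = "homogeneous", reference = c(0, 0, 0),
                         falloff = 100) {
  kind <- match.arg(kind, c("homogeneous", "surface"))
  if (kind == "surface") stopifnot_scalar(falloff, "falloff", 0, strict_lower = TRUE)
  structure(list(kind = kind, reference = as.numeric(reference),
                 falloff = falloff), class = "coil_profile")
}

coil_sensitivity <- function(coil, world) {
  if (coil$kind == "homogeneous") return(rep(1, nrow(world)))
  d <- sqrt(rowSums(sweep(world, 2, coil$reference)^2))
  exp(-d / coil$falloff)
}

band_factor <- function(bands, world) {
  f <- rep(1, nrow(world))
  for (b in bands) {
    dist <- abs(sweep(world, 2, b$centre) %*% b$normal)
    f[dist <= b$thickness / 2] <- f[dist <= b$thickness / 2] * b$suppression
  }
  f
}

#' Evaluate sequence contrast over a resliced stack
#'
#' Applies, per voxel: saturation-band suppression and coil sensitivity to
#' the proton density, then the sequence family's closed-form signal
#' expression. `GRE_SPOILED` evaluates on the T2* map derived from the
#' resliced field-offset map (unless shimming is on); `FSE` uses the
#' spin-echo expression here, its echo-train attenuation being a k-space
#' filter applied later by [apply_etl_attenuation()].
#'
#' @param resliced a `resliced_stack` from [reslice()].
#' @param seq a `sequence_params`.
#' @param bands list of [saturation_band()] objects (may be empty).
#' @param coil a [coil_profile()].
#' @return list of per-slice real contrast matrices (class `contrast_stack`).
#' @export
contrast_stack <- function(resliced, seq, bands = list(),
                           coil = coil_profile("homogeneous")) {
  if (!inherits(resliced, "resliced_stack"))
    abort_invalid("resliced must be a resliced_stack")
  if (!inherits(seq, "sequence_params"))
    abort_invalid("seq must be a sequence_params")
  if (inherits(bands, "saturation_band")) bands <- list(bands)
  geom <- resliced$geometry
  out <- vector("list", length(resliced$slices))
  for (s in seq_along(resliced$slices)) {
    sl <- resliced$slices[[s]]
    world <- slice_world_coords(geom, s)
    pd <- as.vector(sl$pd) * band_factor(bands, world) *
      coil_sensitivity(coil, world)
    db0 <- if (seq$shimming_on) 0 * as.vector(sl$delta_b0)
           else as.vector(sl$delta_b0)
    sig <- switch(seq$family,
      SE = ,
      FSE = signal_se(pd, as.vector(sl$t1), as.vector(sl$t2), seq$te, seq$tr),
      IR_SE = signal_ir(pd, as.vector(sl$t1), as.vector(sl$t2), seq$te,
                        seq$tr, seq$ti),
      GRE_SPOILED = signal_gre_spoiled(
        pd, as.vector(sl$t1),
        t2star_map(as.vector(sl$t2), db0, seq$field_strength_t),
        seq$te, seq$tr, seq$flip_deg))
    out[[s]] <- matrix(sig, nrow(sl$pd), ncol(sl$pd))
  }
  structure(list(slices = out, geometry = geom), class = "contrast_stack")
}
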