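# Isotope notation conversion and mass-balance bookkeeping.
#
# All internal arithmetic is done in (amount, atom fraction) space; delta
# values appear only at the interfaces. Linear mixing of delta values is only
# approximate and breaks down badly at tracer-level enrichment (98 atom-%),
# whereas atom-fraction x amount mixing is exact mass conservation.

#' 15N/14N ratio of atmospheric N2
#'
#' Default isotope reference ratio. The value 0.0036765 reproduces a natural
#' abundance of 0.3663 atom-% 15N at delta-15N = 0 permil.
#'
#' @export
r15n_air <- 0.0036765

#' Convert delta-15N (permil) to 15N atom fraction
#'
#' The atom fraction is `n = R / (1 + R)` with
#' `R = r15_standard * (1 + delta / 1000)`. At `delta = 0` and the
#' atmospheric reference this gives natural abundance, 0.003663
#' (0.3663 atom-%).
#'
#' @param delta delta-15N in permil versus atmospheric N2. Must exceed
#'   -1000 (an 15N-free pool has no finite delta).
#' @param r15_standard reference 15N/14N ratio; default [r15n_air].
#' @return 15N atom fraction in (0, 1), same length as `delta`.
#' @seealso [atom_fraction_to_delta()] for the exact inverse.
#' @examples
#' delta_to_atom_fraction(0)      # natural abundance, 0.003663
#' delta_to_atom_fraction(1000)   # doubled isotope ratio
#' @export
delta_to_atom_fraction <- function(delta, r15_standard = r15n_air) {
  stopifnot(is.numeric(delta), is.numeric(r15_standard), r15_standard > 0)
  if (any(!is.finite(delta)) || any(delta <= -1000)) {
    rlang::abort(
      "`delta` must be finite and greater than -1000 permil.",
      class = "n15rates_invalid_isotope_value"
    )
  }
  r <- r15_standard * (1 + delta / 1000)
  r / (1 + r)
}

#' Convert 15N atom fraction to delta-15N (permil)
#'
#' Exact inverse of [delta_to_atom_fraction()]:
#' `delta = 1000 * (n / (1 - n) / r15_standard - 1)`.
#'
#' @param n 15N atom fraction, strictly inside (0, 1).
#' @inheritParams delta_to_atom_fraction
#' @return delta-15N in permil.
#' @export
atom_fraction_to_delta <- function(n, r15_standard = r15n_air) {
  stopifnot(is.numeric(n), is.numeric(r15_standard), r15_standard > 0)
  if (any(!is.finite(n)) || any(n <= 0) || any(n >= 1)) {
    rlang::abort(
      "Atom fraction `n` must lie strictly inside (0, 1).",
      class = "n15rates_invalid_isotope_value"
    )
  }
  1000 * (n / (1 - n) / r15_standard - 1)
}

#' Natural-abundance 15N atom fraction
#'
#' @inheritParams delta_to_atom_fraction
#' @return atom fraction at delta-15N = 0 (0.003663 for the default
#'   reference).
#' @export
natural_abundance <- function(r15_standard = r15n_air) {
  delta_to_atom_fraction(0, r15_standard)
}

#' Construct a nitrogen-pool table
#'
#' A nitrogen pool is a tibble row holding an amount of nitrogen (`conc`,
#' nmol N per litre, or an absolute amount in nmol when `volume_mL` is
#' supplied) and its 15N atom fraction. Exactly one of `atom_frac` or
#' `delta` must be given.
#'
#' @param conc nitrogen concentration, nmol N per litre (non-negative).
#' @param atom_frac 15N atom fraction in (0, 1).
#' @param delta delta-15N in permil (converted with `r15_standard`).
#' @param label free-text role: substrate, product, tracer, carrier, blank...
#' @param volume_mL optional sample volume; when present, amount-based
#'   operations use `conc * volume_mL / 1000` nmol N.
#' @inheritParams delta_to_atom_fraction
#' @return a tibble with columns `conc`, `atom_frac`, `label`, `volume_mL`.
#' @examples
#' n_pool(20, delta = 0, label = "substrate")
#' n_pool(20, atom_frac = 0.98, label = "tracer")
#' @export
n_pool <- function(conc, atom_frac = NULL, delta = NULL,
                   label = "substrate", volume_mL = NA_real_,
                   r15_standard = r15n_air) {
  if (is.null(atom_frac) == is.null(delta)) {
    rlang::abort("Supply exactly one of `atom_frac` or `delta`.",
                 class = "n15rates_invalid_isotope_value")
  }
  if (is.null(atom_frac)) {
    atom_frac <- delta_to_atom_fraction(delta, r15_standard)
  }
  if (any(conc < 0)) {
    rlang::abort("Pool concentrations must be non-negative.",
                 class = "n15rates_invalid_pool")
  }
  if (any(atom_frac <= 0) || any(atom_frac >= 1)) {
    rlang::abort("Atom fraction must lie strictly inside (0, 1).",
                 class = "n15rates_invalid_isotope_value")
  }
  tibble::tibble(
    conc = as.numeric(conc),
    atom_frac = as.numeric(atom_frac),
    label = label,
    volume_mL = as.numeric(volume_mL)
  )
}

# nmol N held by each pool row: per-litre basis unless a volume is tagged.
pool_amount <- function(pools) {
  amt <- pools$conc
  if ("volume_mL" %in% names(pools)) {
    has_vol <- !is.na(pools$volume_mL)
    amt[has_vol] <- pools$conc[has_vol] * pools$volume_mL[has_vol] / 1000
  }
  amt
}

#' Mix nitrogen pools by exact mass balance
#'
#' Combines pools conserving both total nitrogen and 15N content: the
#' mixture concentration is the sum of the inputs and its atom fraction is
#' the amount-weighted mean. This is how the post-spike substrate labelling
#' f15 is computed when a tracer is added to an ambient pool.
#'
#' @param pools a tibble of pools as built by [n_pool()] (rows are mixed).
#' @return a one-row pool tibble labelled `"mixture"`.
#' @examples
#' ambient <- n_pool(20, delta = 0)
#' tracer <- n_pool(20, atom_frac = 0.98, label = "tracer")
#' mix_pools(dplyr::bind_rows(ambient, tracer)) # f15 of the spiked pool
#' @export
mix_pools <- function(pools) {
  stopifnot(is.data.frame(pools), all(c("conc", "atom_frac") %in% names(pools)))
  if (any(pools$conc < 0)) {
    rlang::abort("Pool concentrations must be non-negative.",
                 class = "n15rates_invalid_pool")
  }
  amt <- pool_amount(pools)
  if (sum(amt) <= 0) {
    rlang::abort("All pool amounts are zero; the mixture is degenerate.",
                 class = "n15rates_degenerate_mixture")
  }
  vol <- if ("volume_mL" %in% names(pools) && !anyNA(pools$volume_mL)) {
    sum(pools$volume_mL)
  } else {
    NA_real_
  }
  conc <- if (is.na(vol)) sum(pools$conc) else sum(amt) / (vol / 1000)
  tibble::tibble(
    conc = conc,
    atom_frac = sum(amt * pools$atom_frac) / sum(amt),
    label = "mixture",
    volume_mL = vol
  )
}

#' Recover a sample pool from a carrier-amended measurement
#'
#' When the analyte is too dilute to measure directly, a carrier standard of
#' known amount and isotopic composition is added and the mixture is
#' measured; the sample's composition follows by mass conservation:
#' `n_sample = (n_mix * N_mix - n_carrier * N_carrier) / N_sample`,
#' computed in (amount, atom fraction) space rather than as a delta-linear
#' approximation.
#'
#' @param mixture one-row pool tibble: the measured carrier + sample mixture.
#' @param carrier one-row pool tibble: the added carrier standard.
#' @param sample_amount nitrogen amount of the sample, nmol. Defaults to
#'   mixture amount minus carrier amount; if supplied it must agree with
#'   that difference within `tol` (relative).
#' @param tol relative tolerance for the amount-balance check.
#' @return a one-row pool tibble labelled `"sample"` whose `conc` is the
#'   sample amount in nmol.
#' @export
unmix_carrier <- function(mixture, carrier, sample_amount = NULL, tol = 1e-6) {
  n_mix <- pool_amount(mixture)
  n_car <- pool_amount(carrier)
  stopifnot(length(n_mix) == 1, length(n_car) == 1)
  if (n_mix <= n_car) {
    rlang::abort("Mixture amount must exceed the carrier amount.",
                 class = "n15rates_unmixing_infeasible")
  }
  n_smp <- n_mix - n_car
  if (!is.null(sample_amount)) {
    if (abs(sample_amount - n_smp) > tol * max(n_mix, 1)) {
      rlang::abort(
        "`sample_amount` is inconsistent with mixture minus carrier.",
        class = "n15rates_unmixing_infeasible"
      )
    }
    n_smp <- sample_amount
  }
  af <- (mixture$atom_frac * n_mix - carrier$atom_frac * n_car) / n_smp
  if (!is.finite(af) || af <= 0 || af >= 1) {
    rlang::abort(
      "Unmixing gives an unphysical sample atom fraction (blank-dominated sample?).",
      class = "n15rates_unmixing_infeasible"
    )
  }
  tibble::tibble(conc = n_smp, atom_frac = af, label = "sample",
                 volume_mL = NA_real_)
}

#' Subtract procedural blanks from a measured pool
#'
#' Removes the nitrogen amount and 15N content contributed by each blank
#' (e.g. the persulfate oxidizing reagent and unused filters in particulate
#' nitrogen digestion) by mass balance. Warns when the blanks exceed 3% of
#' the measured nitrogen, the level below which blank contributions are
#' conventionally considered negligible.
#'
#' @param measured one-row pool tibble: the measured (sample + blanks) pool,
#'   amounts in nmol N.
#' @param blanks pool tibble, one row per blank.
#' @param warn_fraction blank fraction above which a warning is raised.
#' @return one-row pool tibble of the blank-corrected sample, with an extra
#'   `blank_fraction` column.
#' @export
correct_blanks <- function(measured, blanks, warn_fraction = 0.03) {
  n_meas <- pool_amount(measured)
  stopifnot(length(n_meas) == 1)
  if (nrow(blanks) == 0 || sum(pool_amount(blanks)) == 0) {
    out <- measured
    out$blank_fraction <- 0
    return(out)
  }
  n_blk <- pool_amount(blanks)
  if (sum(n_blk) >= n_meas) {
    rlang::abort("Blanks exceed the measured nitrogen amount.",
                 class = "n15rates_blank_exceeds_sample")
  }
  frac <- sum(n_blk) / n_meas
  if (frac > warn_fraction) {
    rlang::warn(
      sprintf("Blanks are %.1f%% of the measured N (above %.0f%%).",
              100 * frac, 100 * warn_fraction),
      class = "n15rates_blank_fraction_warning"
    )
  }
  amt <- n_meas - sum(n_blk)
  content15 <- n_meas * measured$atom_frac - sum(n_blk * blanks$atom_frac)
  af <- content15 / amt
  if (!is.finite(af) || af <= 0 || af >= 1) {
    rlang::abort("Blank correction gives an unphysical atom fraction.",
                 class = "n15rates_blank_exceeds_sample")
  }
  tibble::tibble(conc = amt, atom_frac = af, label = measured$label,
                 volume_mL = NA_real_, blank_fraction = frac)
}
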