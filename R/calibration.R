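#' Default model calibration
#'
#' All free numerical parameters of the model live here, in one place: field
#' transport coefficients, secretion amounts, activation thresholds, lifespans
#' and the injection dose.  None of these quantities is measured; they are
#' model calibration constants, chosen once so that the default run (101 x 101
#' lobule, injections every 10 steps for 120 steps) reproduces the reference
#' dynamics of the fibrosis sequence: pericentral necrosis beginning at the
#' second injection, a single inflammatory burst after the third injection,
#' myofibroblast collagen rising shortly after the burst, and no ignition at
#' all when only two injections are given or when the injection interval is
#' stretched to 18 steps.
#'
#' Concentrations are in arbitrary units; every threshold is 1 except the
#' stellate-cell TNF-alpha threshold, which is slightly lower so that
#' myofibroblast transformation slightly leads apoptosis in the same TNF-alpha
#' gradient.
#'
#' @return Named list of calibration constants, see source for the meaning of
#'   each entry.
#' @export
default_calibration <- function() {
  list(
    fields = list(
      # share = fraction of a cell's value redistributed to its 8 neighbours
      # per step; decay = first-order loss per step.
      ccl4  = list(share = 0.30, decay = 0.08),
      hmgb1 = list(share = 0.30, decay = 0.03),
      tnf   = list(share = 0.70, decay = 0.22),
      tgf   = list(share = 0.70, decay = 0.02)
    ),
    thresholds = list(
      ccl4_hep = 1.0,  # effective (zonation-weighted) toxin killing a hepatocyte
      tnf_hep  = 1.0,  # TNF-alpha concentration inducing apoptosis
      hmgb1_kc = 9.0,  # HMGB1 concentration activating a quiescent Kupffer cell
      tnf_hsc  = 0.3,  # TNF-alpha concentration transforming an HSC
      tgf_fib  = 1.0   # TGF-beta concentration triggering collagen secretion
    ),
    secretion = list(
      hmgb1 = 0.60,    # per necrotic dead cell per step
      tnf   = 0.80,    # per M1 Kupffer cell per step
      tgf   = 0.90     # per M2 Kupffer cell per step
    ),
    tau_m1m2 = 4L,     # steps an activated KC spends in the M1 phenotype
    lifespans = list(
      hepatocyte         = 1000000L,
      dead               = 11L,
      kupffer            = 600L,
      hsc                = 1000000L,
      myofibroblast      = 1000000L,
      portal_fibroblast  = 1000000L
    ),
    replication_cooldown    = 4L,   # steps before a hepatocyte may divide again
    collagen_rich_threshold = 2L,   # neighbouring deposits blocking division
    max_collagen_per_mfb    = 3L,   # deposits before a myofibroblast dies of production
    kc_replenish_rate       = 0.5,  # P(new quiescent KC) per portal tract per step
    dose                    = 2200  # toxin mass per injection (arbitrary units)
  )
}
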