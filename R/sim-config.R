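#' Configuration of the mechanistic runoff simulator
#'
#' Parameters of the simulated cell: an mRNA population with lognormal coding
#' lengths, ribosomes loaded at a mean spacing with a hard exclusion
#' footprint, a deterministic elongation speed, and a fraction of
#' ribosome-bearing mRNAs sequestered as translationally inactive granules
#' (which harringtonine runoff does not empty).
#'
#' @param n_mrnas Number of mRNAs in the population.
#' @param length_meanlog,length_sdlog Lognormal parameters of coding length
#'   in codons (defaults give a ~500-codon mean, typical of mammalian CDS).
#' @param ribosome_spacing Mean codons between loaded ribosomes (loading
#'   density); must be >= `exclusion_footprint`.
#' @param elongation_rate Ribosome speed v in codons/s.
#' @param f_inactive Fraction in `[0, 1]` of ribosome-bearing mRNAs frozen as
#'   inactive granules.
#' @param hrn_stall_at_start Should harringtonine leave one immobilised 80S at
#'   the start codon of each active mRNA (drawn from the free 80S pool)?
#' @param exclusion_footprint Minimum codons between adjacent ribosomes.
#' @param free_80s_frac Free (non-translating) 80S pool at steady state, as a
#'   fraction of the loaded ribosome count; these sediment with the monosome
#'   peak and supply the harringtonine-stalled start-codon 80S.
#' @param noise_sd Gaussian measurement noise of synthesised traces (A254).
#' @param nmda_delta_f Additional inactive fraction recruited by NMDA
#'   stimulation (0 = treatment is a no-op, as in immature neurons).
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_mrnas = 2000,
                       length_meanlog = log(450),
                       length_sdlog = 0.45,
                       ribosome_spacing = 90,
                       elongation_rate = 2,
                       f_inactive = 0.1,
                       hrn_stall_at_start = TRUE,
                       exclusion_footprint = 10,
                       free_80s_frac = 0.4,
                       noise_sd = 0.002,
                       nmda_delta_f = 0,
                       seed = 1L) {
  cfg <- list(
    n_mrnas = as.integer(n_mrnas),
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    ribosome_spacing = ribosome_spacing,
    elongation_rate = elongation_rate,
    f_inactive = f_inactive,
    hrn_stall_at_start = isTRUE(hrn_stall_at_start),
    exclusion_footprint = exclusion_footprint,
    free_80s_frac = free_80s_frac,
    noise_sd = noise_sd,
    nmda_delta_f = nmda_delta_f,
    seed = as.integer(seed)
  )
  if (cfg$n_mrnas < 1L) stop_parameter("n_mrnas must be >= 1")
  if (cfg$elongation_rate <= 0) stop_parameter("elongation_rate must be > 0")
  if (cfg$ribosome_spacing < cfg$exclusion_footprint) {
    stop_parameter("ribosome_spacing must be >= exclusion_footprint")
  }
  if (cfg$f_inactive < 0 || cfg$f_inactive > 1) {
    stop_parameter("f_inactive must be in [0, 1]")
  }
  if (cfg$f_inactive + cfg$nmda_delta_f > 1) {
    stop_parameter("f_inactive + nmda_delta_f must be <= 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Cell-type presets for the runoff simulator
#'
#' Named parameter sets spanning the qualitative regimes the runoff assay
#' distinguishes: fast ribosomes with almost no inactive pool (`hek`), slower
#' stem-cell ribosomes (`hnsc`), immature neurons (`rcn_immature`), mature
#' neurons with fast ribosomes but a large inactive-granule pool
#' (`rcn_mature`), and NMDA-stimulated mature neurons (`rcn_mature_nmda`,
#' which additionally recruits active mRNAs into granules). The inactive
#' fractions are illustrative defaults -- the assay itself estimates them via
#' the fitted plateau -- and the speeds are chosen so the decline resolves on
#' a 0-10 min sampling grid.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [sim_config()].
#' @return A [sim_config()].
#' @export
#' @examples
#' sim_preset("rcn_mature", n_mrnas = 500, seed = 7)
sim_preset <- function(name = c("hek", "hnsc", "rcn_immature", "rcn_mature",
                                "rcn_mature_nmda"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    hek = list(elongation_rate = 2.5, f_inactive = 0.02),
    hnsc = list(elongation_rate = 1.2, f_inactive = 0.08),
    rcn_immature = list(elongation_rate = 1.0, f_inactive = 0.12),
    rcn_mature = list(elongation_rate = 3.0, f_inactive = 0.35),
    rcn_mature_nmda = list(elongation_rate = 3.0, f_inactive = 0.35,
                           nmda_delta_f = 0.15)
  )
  cfg <- do.call(sim_config, modifyList(base, list(...)))
  attr(cfg, "preset") <- name
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config>%s %d mRNAs | v = %g codons/s | spacing %g | f_inactive = %g | seed %d\n",
              if (!is.null(attr(x, "preset"))) paste0(" [", attr(x, "preset"), "]") else "",
              x$n_mrnas, x$elongation_rate, x$ribosome_spacing, x$f_inactive,
              x$seed))
  invisible(x)
}
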