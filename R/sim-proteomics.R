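#' Simulate a fraction-resolved iBAQ abundance matrix
#'
#' Generates proteins x samples intensities for a two-fraction
#' (monosome/polysome) by two-treatment (CHX/HRN) design with replicates.
#' Per-protein baselines are lognormal on the iBAQ scale; planted effects are
#' specified in log2 units as a polysome-enrichment term (polysome vs
#' monosome under CHX) and a runoff-shift term (HRN-polysome vs CHX-polysome).
#' Noise is multiplicative (log-normal) plus additive (detector floor), which
#' makes low-intensity variances blow up on a plain log scale -- the regime a
#' variance-stabilising transform is for. Missingness is mixed: values below
#' an intensity threshold are censored (MNAR), and a random fraction of the
#' remainder is masked (MAR). The planted truth is attached as the
#' `ground_truth` attribute.
#'
#' @param n_proteins Number of proteins.
#' @param n_rep Replicates per (fraction, treatment) condition (>= 2).
#' @param planted Optional tibble with columns `protein_id`,
#'   `poly_enrichment_log2` (CHX polysome vs CHX monosome) and
#'   `runoff_shift_log2` (HRN polysome vs CHX polysome); unlisted proteins
#'   get zero effects.
#' @param base_meanlog2,base_sdlog2 Baseline log2-intensity distribution.
#' @param noise_sd_log2 Multiplicative noise SD (log2 units).
#' @param additive_sd Additive detector noise SD (intensity units).
#' @param mar_rate Fraction of observed entries masked at random.
#' @param mnar_quantile Intensity quantile below which entries are censored.
#' @param seed Integer seed.
#' @return An [abundance_table()] (stage `"raw"`) with a `ground_truth`
#'   attribute.
#' @export
simulate_proteomics <- function(n_proteins = 2000, n_rep = 3, planted = NULL,
                                base_meanlog2 = 23, base_sdlog2 = 2.5,
                                noise_sd_log2 = 0.25, additive_sd = 2^15,
                                mar_rate = 0, mnar_quantile = 0,
                                seed = 1L) {
  if (n_rep < 2) stop_design("at least 2 replicates per condition are required")
  set.seed(as.integer(seed))
  design <- tidyr::expand_grid(
    fraction = c("monosome", "polysome"),
    treatment = c("CHX", "HRN"),
    replicate = seq_len(n_rep)
  )
  design$sample_id <- sprintf("%s_%s_r%d",
                              substr(design$fraction, 1, 4),
                              design$treatment, design$replicate)
  protein_id <- sprintf("P%04d", seq_len(n_proteins))

  beta_poly <- setNames(rep(0, n_proteins), protein_id)
  beta_shift <- setNames(rep(0, n_proteins), protein_id)
  if (!is.null(planted)) {
    stopifnot(all(planted$protein_id %in% protein_id))
    if ("poly_enrichment_log2" %in% names(planted)) {
      beta_poly[planted$protein_id] <- planted$poly_enrichment_log2
    }
    if ("runoff_shift_log2" %in% names(planted)) {
      beta_shift[planted$protein_id] <- planted$runoff_shift_log2
    }
  }

  mu <- rnorm(n_proteins, base_meanlog2, base_sdlog2)
  n_s <- nrow(design)
  m <- matrix(NA_real_, n_proteins, n_s,
              dimnames = list(protein_id, design$sample_id))
  for (j in seq_len(n_s)) {
    is_poly <- design$fraction[j] == "polysome"
    is_hrn <- design$treatment[j] == "HRN"
    lmu <- mu + if (is_poly) beta_poly else 0
    lmu <- lmu + if (is_poly && is_hrn) beta_shift else 0
    m[, j] <- 2^(lmu + rnorm(n_proteins, 0, noise_sd_log2)) +
      rnorm(n_proteins, 0, additive_sd)
  }
  m <- pmax(m, 1)

  if (mnar_quantile > 0) {
    thr <- quantile(m, mnar_quantile)
    m[m < thr] <- NA_real_
  }
  if (mar_rate > 0) {
    mask <- matrix(runif(length(m)) < mar_rate, nrow(m))
    m[mask] <- NA_real_
  }

  tab <- abundance_table(m, design)
  attr(tab, "ground_truth") <- tibble(
    protein_id = protein_id,
    poly_enrichment_log2 = unname(beta_poly),
    runoff_shift_log2 = unname(beta_shift)
  )
  tab
}
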