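test_that("steady-state initialisation matches its Poisson loading model", {
  # sparse loading: spacing = mean length => ~1 ribosome per mRNA
  cfg <- sim_config(n_mrnas = 10000, length_meanlog = log(400),
                    length_sdlog = 0.01, ribosome_spacing = 400,
                    f_inactive = 0, seed = 9)
  st <- init_steady_state(cfg)
  expect_equal(nrow(st$ribosomes) / cfg$n_mrnas, 1, tolerance = 0.1)

  # exclusion footprint respected within every mRNA
  gaps <- dplyr::summarise(dplyr::group_by(st$ribosomes, mrna),
                           min_gap = if (dplyr::n() > 1) min(diff(sort(pos))) else Inf)
  expect_gte(min(gaps$min_gap), cfg$exclusion_footprint)

  expect_error(sim_config(ribosome_spacing = 5, exclusion_footprint = 10),
               class = "parameter_error")
})

test_that("initialisation is deterministic under a fixed seed", {
  cfg <- sim_config(n_mrnas = 500, seed = 123)
  expect_identical(init_steady_state(cfg), init_steady_state(cfg))
  sim1 <- simulate_timecourse(cfg, times = c(0, 5))
  sim2 <- simulate_timecourse(cfg, times = c(0, 5))
  expect_identical(sim1$series$value, sim2$series$value)
  expect_identical(sim1$traces[[2]]$a254, sim2$traces[[2]]$a254)
})

test_that("runoff obeys the transit-time rule and its limits", {
  cfg <- sim_config(n_mrnas = 300, f_inactive = 0, seed = 4)
  st <- init_steady_state(cfg)
  expect_identical(apply_runoff(st, 0, cfg), st)

  # complete runoff: every active mRNA retains only the stalled start 80S
  long_t <- max(st$mrnas$length) / cfg$elongation_rate / 60 + 1
  done <- apply_runoff(st, long_t, cfg)
  expect_equal(nrow(done$ribosomes), 0)
  expect_true(all(done$mrnas$stalled == 1L))
  cs <- census(done)
  expect_equal(polysome_ribosomes(cs), 0)
  expect_true(conservation_holds(done))

  # runoff composes additively in time
  two_step <- apply_runoff(apply_runoff(st, 2, cfg), 3, cfg)
  one_step <- apply_runoff(st, 5, cfg)
  expect_equal(sort(two_step$ribosomes$pos), sort(one_step$ribosomes$pos))
  expect_equal(two_step$free_80S, one_step$free_80S)
})

test_that("fully inactive populations ignore runoff", {
  cfg <- sim_config(n_mrnas = 400, f_inactive = 1, seed = 6)
  st <- init_steady_state(cfg)
  after <- apply_runoff(st, 30, cfg)
  expect_identical(after$ribosomes, st$ribosomes)
  expect_equal(polysome_ribosomes(census(after)),
               polysome_ribosomes(census(st)))
})

test_that("linear-regime runoff matches the closed-form 1 - vt/L", {
  # fixed length, uniform positions, no exclusion effects at sparse loading
  cfg <- sim_config(n_mrnas = 10000, length_meanlog = log(600),
                    length_sdlog = 1e-9, ribosome_spacing = 600,
                    elongation_rate = 5, f_inactive = 0,
                    exclusion_footprint = 1, hrn_stall_at_start = FALSE,
                    seed = 11)
  st <- init_steady_state(cfg)
  n0 <- nrow(st$ribosomes)
  after <- apply_runoff(st, 1, cfg)  # vt = 300 codons, L = 600
  expect_equal(nrow(after$ribosomes) / n0, 0.5, tolerance = 0.02)
})

test_that("treatments transform species counts as specified", {
  cfg <- sim_config(n_mrnas = 300, f_inactive = 0.3, seed = 21)
  st <- init_steady_state(cfg)
  total <- st$total_ribosomes

  edta <- apply_treatment(st, "EDTA", cfg)
  cs <- census(edta)
  expect_equal(nrow(cs$nsome), 0)
  expect_equal(cs$subunits, 2 * total)
  expect_true(conservation_holds(edta))

  pmy <- apply_treatment(st, "PMY", cfg)
  cs_pmy <- census(pmy)
  # granules are PMY-insensitive, active ribosomes released as free 80S
  expect_equal(cs_pmy$granule_ribosomes, census(st)$granule_ribosomes)
  expect_equal(sum(cs_pmy$nsome$n * cs_pmy$nsome$count), 0)
  expect_true(conservation_holds(pmy))
})

test_that("RNase1 digestion yields n monosomes per n-some and over-digests", {
  # deterministic arithmetic at the optimal dose: 100 active 3-somes +
  # 50 monosomes -> 350 monosomes
  mk_state <- function() {
    mrnas <- tibble::tibble(mrna = 1:150,
                            length = rep(300, 150),
                            class = "active",
                            stalled = 0L)
    ribos <- dplyr::bind_rows(
      tibble::tibble(mrna = rep(1:100, each = 3),
                     pos = rep(c(10, 100, 200), 100)),
      tibble::tibble(mrna = 101:150, pos = 50)
    )
    st <- list(mrnas = mrnas, ribosomes = ribos, free_80S = 0L,
               free_subunits = 0L, footprint = 10)
    st$total_ribosomes <- 350
    class(st) <- "cell_state"
    st
  }
  cfg <- sim_config(seed = 1)
  dig <- apply_treatment(mk_state(), "RNase1", cfg, units = 19, u_opt = 19)
  cs <- census(dig)
  expect_equal(cs$nsome, tibble::tibble(n = 1L, count = 350L))

  # over-digestion: higher dose destroys monosomes (in expectation and
  # via the dose-response law itself)
  set.seed(99)
  over <- apply_treatment(mk_state(), "RNase1", cfg, units = 60, u_opt = 19)
  expect_lt(sum(census(over)$nsome$count), 350)
  p_over <- function(u, u_opt = 19, lambda = 0.5 / 19) {
    1 - exp(-lambda * max(0, u - u_opt))
  }
  expect_equal(p_over(19), 0)
  expect_gt(p_over(38), p_over(19))
  expect_gt(p_over(57), p_over(38))
})

test_that("NMDA recruits active mRNAs into granules only when delta_f > 0", {
  cfg <- sim_preset("rcn_mature_nmda", n_mrnas = 2000, seed = 31)
  st <- init_steady_state(cfg)
  set.seed(1)
  after <- apply_treatment(st, "NMDA", cfg)
  expect_gt(sum(after$mrnas$class == "inactive_granule"),
            sum(st$mrnas$class == "inactive_granule"))

  cfg0 <- sim_preset("rcn_immature", n_mrnas = 500, seed = 31)
  st0 <- init_steady_state(cfg0)
  expect_identical(apply_treatment(st0, "NMDA", cfg0), st0)

  expect_error(apply_treatment(st, "heat", cfg), class = "parameter_error")
})

test_that("integer ribosome conservation holds through treatment chains", {
  for (seed in 1:60) {
    cfg <- sim_config(n_mrnas = 120, f_inactive = runif(1, 0, 0.6),
                      seed = seed)
    st <- init_steady_state(cfg)
    t_run <- sample(c(0.5, 2, 10), 1)
    run <- apply_runoff(st, t_run, cfg)
    expect_true(conservation_holds(run))
    expect_true(conservation_holds(apply_treatment(run, "EDTA", cfg)))
    expect_true(conservation_holds(apply_treatment(run, "PMY", cfg)))
  }
})

test_that("trace synthesis reproduces analytic species signal", {
  counts <- structure(list(
    nsome = tibble::tibble(n = 1L, count = 100L),
    granule_nsome = tibble::tibble(n = integer(0), count = integer(0)),
    free_80S = 0L, subunits = 0L, granule_ribosomes = 0L,
    total_80S_equivalents = 100
  ), class = "species_counts")
  geom <- trace_geometry()
  tr <- synthesize_trace(counts, geom, noise_sd = 0)
  corrected <- correct_baseline(tr)
  auc <- pracma::trapz(corrected$position_mm, corrected$a254)
  expect_equal(auc, 100 * 2 * geom$au_per_unit, tolerance = 0.01)
  pk <- detect_peaks(corrected, min_prominence = 0.01)
  expect_equal(pk$center_mm[pk$label == "80S"], geom$mu_80S, tolerance = 0.1)

  empty <- counts
  empty$nsome <- counts$granule_nsome
  empty$total_80S_equivalents <- 0
  tr0 <- synthesize_trace(empty, geom, noise_sd = 0)
  expect_equal(tr0$a254, geom$baseline + geom$baseline_slope * tr0$position_mm,
               tolerance = 1e-12)
})

test_that("quantified P/M tracks the RNA-weighted ground truth within 3 %", {
  cfg <- sim_config(n_mrnas = 5000, f_inactive = 0.25, seed = 14)
  st <- init_steady_state(cfg)
  cs <- census(st)
  gt <- ground_truth_signal(cs)
  tr <- synthesize_trace(cs, noise_sd = cfg$noise_sd, seed = 15,
                         sample_id = "gt", treatment = "CHX")
  q <- quantify_trace(tr)
  expect_equal(q$pm_ratio, gt$pm_ratio, tolerance = 0.03)
  expect_equal(q$polysome_auc, gt$polysome_signal, tolerance = 0.03)
})

test_that("timecourse fold changes plateau at the inactive fraction", {
  cfg <- sim_config(n_mrnas = 10000, f_inactive = 0.4, seed = 8)
  sim <- simulate_timecourse(cfg, times = c(0, 1, 5, 10, 20))
  expect_equal(sim$series$value[1], 1)
  expect_true(all(diff(sim$series$value) <= 1e-9))
  expect_equal(sim$series$value[length(sim$series$value)], 0.4,
               tolerance = 0.125)  # +-0.05 absolute on 0.4

  cfg0 <- sim_config(n_mrnas = 3000, f_inactive = 0, seed = 8)
  sim0 <- simulate_timecourse(cfg0, times = c(0, 20))
  expect_lt(sim0$series$value[2], 0.05)
})

test_that("pipeline series matches simulator ground truth within 3 %", {
  cfg <- sim_config(n_mrnas = 8000, f_inactive = 0.3, seed = 17)
  sim <- simulate_timecourse(cfg)
  q <- quantify_traces(sim$traces)
  ser <- build_series(q, "polysome")
  expect_lt(max(abs(ser$value - sim$series$value)), 0.03)
})

test_that("NMDA preset raises post-runoff polysomes and lowers 80S/disomes", {
  wins <- 0L
  for (seed in 1:20) {
    ctrl_cfg <- sim_preset("rcn_mature", n_mrnas = 1500, seed = seed)
    nmda_cfg <- sim_preset("rcn_mature_nmda", n_mrnas = 1500, seed = seed)
    st_c <- init_steady_state(ctrl_cfg)
    st_n <- init_steady_state(nmda_cfg)
    set.seed(seed)
    st_n <- apply_treatment(st_n, "NMDA", nmda_cfg)
    run_c <- census(apply_runoff(st_c, 10, ctrl_cfg))
    run_n <- census(apply_runoff(st_n, 10, nmda_cfg))
    poly_up <- polysome_ribosomes(run_n) > polysome_ribosomes(run_c)
    mono_count <- function(cs) {
      sum(cs$nsome$count[cs$nsome$n == 1]) + cs$free_80S
    }
    mono_down <- mono_count(run_n) < mono_count(run_c)
    wins <- wins + (poly_up && mono_down)
  }
  expect_gte(wins, 18)
})

test_that("proteomics simulator is reproducible and plants its effects", {
  pl <- tibble::tibble(protein_id = c("P0001", "P0002"),
                       poly_enrichment_log2 = c(2, 0),
                       runoff_shift_log2 = c(0, -2))
  t1 <- simulate_proteomics(n_proteins = 50, n_rep = 3, planted = pl, seed = 3)
  t2 <- simulate_proteomics(n_proteins = 50, n_rep = 3, planted = pl, seed = 3)
  expect_identical(t1$intensities, t2$intensities)
  gt <- attr(t1, "ground_truth")
  expect_equal(gt$poly_enrichment_log2[1], 2)
  expect_equal(gt$runoff_shift_log2[2], -2)

  des <- t1$design
  poly_chx <- rowMeans(t1$intensities[, des$fraction == "polysome" &
                                        des$treatment == "CHX"])
  mono_chx <- rowMeans(t1$intensities[, des$fraction == "monosome" &
                                        des$treatment == "CHX"])
  expect_gt(log2(poly_chx["P0001"] / mono_chx["P0001"]), 1)

  miss <- simulate_proteomics(n_proteins = 200, n_rep = 3, mar_rate = 0.1,
                              mnar_quantile = 0.05, seed = 4)
  expect_gt(mean(is.na(miss$intensities)), 0.1)
})
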