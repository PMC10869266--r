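#' Initialise the pre-runoff steady state
#'
#' Draws the mRNA population and loads ribosomes: each mRNA of length L
#' codons receives Poisson(L / spacing) ribosomes (truncated to the densest
#' feasible packing), placed uniformly at random subject to the hard
#' exclusion footprint. A fraction `f_inactive` of ribosome-bearing mRNAs is
#' then relabelled as inactive granules. A free 80S pool (fraction
#' `free_80s_frac` of the loaded count) completes the state. Deterministic
#' under the config seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `"cell_state"` with elements `mrnas` (tibble:
#'   `mrna`, `length`, `class`, `stalled`), `ribosomes` (tibble: `mrna`,
#'   `pos` in codons), `free_80S`, `free_subunits`, `footprint` and
#'   `total_ribosomes` (the conserved 80S-equivalent total).
#' @export
init_steady_state <- function(config) {
  if (!inherits(config, "sim_config")) stop_parameter("config must be a sim_config")
  set.seed(config$seed)
  n <- config$n_mrnas
  len <- pmax(30, round(rlnorm(n, config$length_meanlog, config$length_sdlog)))
  fp <- config$exclusion_footprint
  n_ribo <- rpois(n, len / config$ribosome_spacing)
  max_fit <- floor(len / fp) + 1L
  n_ribo <- pmin(n_ribo, max_fit)

  total <- sum(n_ribo)
  mrna_of <- rep.int(seq_len(n), n_ribo)
  # uniform placement with hard-core exclusion: sorted uniforms on the
  # footprint-reduced interval plus cumulative footprint offsets
  span <- pmax(len - (n_ribo - 1L) * fp, 0)[mrna_of]
  u <- runif(total) * span
  ord <- order(mrna_of, u)
  u <- u[ord]
  rank_in <- sequence(n_ribo)
  pos <- u + (rank_in - 1) * fp

  loaded <- which(n_ribo > 0L)
  n_inactive <- round(config$f_inactive * length(loaded))
  inactive <- if (n_inactive > 0) sample(loaded, n_inactive) else integer(0)
  cls <- rep("active", n)
  cls[inactive] <- "inactive_granule"

  state <- list(
    mrnas = tibble(mrna = seq_len(n), length = as.numeric(len), class = cls,
                   stalled = rep(0L, n)),
    ribosomes = tibble(mrna = mrna_of, pos = pos),
    free_80S = round(config$free_80s_frac * total),
    free_subunits = 0L,
    footprint = fp
  )
  state$total_ribosomes <- state_total_ribosomes(state)
  class(state) <- "cell_state"
  state
}

state_total_ribosomes <- function(state) {
  nrow(state$ribosomes) + sum(state$mrnas$stalled) + state$free_80S +
    state$free_subunits / 2
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> %d mRNAs (%d inactive granules) | %d loaded ribosomes | %d stalled | %d free 80S | %d subunits\n",
              nrow(x$mrnas), sum(x$mrnas$class == "inactive_granule"),
              nrow(x$ribosomes), sum(x$mrnas$stalled), x$free_80S,
              x$free_subunits))
  invisible(x)
}

#' Apply harringtonine runoff for a given time
#'
#' Ribosomes on active mRNAs elongate deterministically at v codons/s; a
#' ribosome at codon x terminates (joining the free 80S pool) iff it reaches
#' the stop codon within the runoff time, i.e. `(L - x) / v <= 60 t`.
#' Remaining ribosomes advance by `60 t v` codons, so sequential application
#' composes additively in t and the operation is idempotent once t exceeds
#' the longest transit time. If `hrn_stall_at_start` is set and `t > 0`, each
#' active mRNA additionally retains one harringtonine-immobilised 80S at the
#' start codon (taken from the free pool, which at steady state is ample).
#' Inactive-granule mRNAs are untouched. Ribosome count is conserved exactly.
#'
#' @param state A [init_steady_state()] cell state.
#' @param t Runoff time in minutes, >= 0. `t = 0` returns the state unchanged.
#' @param config The [sim_config()] (for `elongation_rate` and stalling).
#' @return The evolved `cell_state`.
#' @export
apply_runoff <- function(state, t, config) {
  if (t < 0) stop_parameter("t must be >= 0")
  if (t == 0) return(state)
  dist <- 60 * t * config$elongation_rate  # codons travelled
  active_mrna <- state$mrnas$mrna[state$mrnas$class == "active"]
  on_active <- state$ribosomes$mrna %in% active_mrna
  L <- state$mrnas$length[state$ribosomes$mrna]
  runs_off <- on_active & (L - state$ribosomes$pos) <= dist
  n_off <- sum(runs_off)
  ribos <- state$ribosomes[!runs_off, , drop = FALSE]
  adv <- ribos$mrna %in% active_mrna
  ribos$pos[adv] <- ribos$pos[adv] + dist
  state$ribosomes <- ribos
  state$free_80S <- state$free_80S + n_off
  if (config$hrn_stall_at_start) {
    need <- state$mrnas$class == "active" & state$mrnas$stalled == 0L
    n_stall <- min(sum(need), state$free_80S)
    if (n_stall > 0) {
      idx <- which(need)[seq_len(n_stall)]
      state$mrnas$stalled[idx] <- 1L
      state$free_80S <- state$free_80S - n_stall
    }
  }
  state
}

#' Apply an in-silico biochemical treatment
#'
#' * `EDTA` dissociates every ribosome in the lysate -- on-mRNA (active and
#'   granule), stalled, and free 80S -- into free 40S/60S subunits.
#' * `PMY` (puromycin) releases elongating ribosomes on active mRNAs into the
#'   free 80S pool; harringtonine-stalled start-codon 80S (no nascent chain)
#'   and inactive granules are insensitive.
#' * `RNase1` cleaves active mRNAs between ribosomes, converting each active
#'   n-some into n monosomes (stalled 80S included); granule ribosomes are
#'   destroyed without producing footprints. Beyond the calibrated dose
#'   `u_opt`, monosomes themselves are destroyed with probability
#'   `p_over(units) = 1 - exp(-lambda * max(0, units - u_opt))`, reproducing
#'   the over-digestion regime where more enzyme yields fewer monosomes.
#' * `NMDA` recruits additional active ribosome-bearing mRNAs into inactive
#'   granules until the inactive fraction reaches
#'   `f_inactive + nmda_delta_f`; with `nmda_delta_f = 0` (immature preset)
#'   it is a no-op.
#'
#' RNase1 and NMDA draw from the current RNG stream; seed upstream for
#' reproducibility.
#'
#' @param state A `cell_state`.
#' @param treatment One of `"EDTA"`, `"PMY"`, `"RNase1"`, `"NMDA"`.
#' @param config The [sim_config()].
#' @param units RNase1 dose in enzyme units (see [rnase_units()]).
#' @param u_opt Calibrated optimal RNase1 dose (units).
#' @param lambda Over-digestion rate; default `0.5 / u_opt`.
#' @return The treated `cell_state`.
#' @export
apply_treatment <- function(state, treatment, config,
                            units = NULL, u_opt = 19, lambda = NULL) {
  if (!treatment %in% c("EDTA", "PMY", "RNase1", "NMDA")) {
    stop_parameter(sprintf("unknown treatment '%s'", treatment))
  }
  if (treatment == "EDTA") {
    n80 <- nrow(state$ribosomes) + sum(state$mrnas$stalled) + state$free_80S
    state$ribosomes <- state$ribosomes[0, , drop = FALSE]
    state$mrnas$stalled <- 0L
    state$free_80S <- 0L
    state$free_subunits <- state$free_subunits + 2L * n80
    return(state)
  }
  if (treatment == "PMY") {
    active_mrna <- state$mrnas$mrna[state$mrnas$class == "active"]
    on_active <- state$ribosomes$mrna %in% active_mrna
    state$free_80S <- state$free_80S + sum(on_active)
    state$ribosomes <- state$ribosomes[!on_active, , drop = FALSE]
    return(state)
  }
  if (treatment == "RNase1") {
    if (is.null(units) || units < 0) stop_parameter("RNase1 requires units >= 0")
    if (is.null(lambda)) lambda <- 0.5 / u_opt
    active <- state$mrnas$class == "active"
    active_ids <- state$mrnas$mrna[active]
    on_active <- state$ribosomes$mrna %in% active_ids
    n_mono <- sum(on_active) + sum(state$mrnas$stalled[active])
    # granule ribosomes are destroyed: no footprints, no subunits
    state$ribosomes <- state$ribosomes[0, , drop = FALSE]
    state$mrnas <- state$mrnas[0, , drop = FALSE]
    p_over <- 1 - exp(-lambda * max(0, units - u_opt))
    survivors <- if (n_mono > 0) stats::rbinom(1, n_mono, 1 - p_over) else 0L
    # each surviving footprint-protected monosome becomes its own fragment
    if (survivors > 0) {
      state$mrnas <- tibble(mrna = seq_len(survivors),
                            length = rep(as.numeric(state$footprint), survivors),
                            class = rep("active", survivors),
                            stalled = rep(0L, survivors))
      state$ribosomes <- tibble(mrna = seq_len(survivors), pos = rep(0, survivors))
    }
    return(state)
  }
  # NMDA
  delta <- config$nmda_delta_f
  if (delta <= 0) return(state)
  loaded <- unique(state$ribosomes$mrna)
  loaded_rows <- which(state$mrnas$mrna %in% loaded |
                         (state$mrnas$stalled > 0L))
  inactive_rows <- which(state$mrnas$class == "inactive_granule")
  target <- round((config$f_inactive + delta) * length(loaded_rows))
  n_extra <- target - length(inactive_rows)
  candidates <- setdiff(loaded_rows, inactive_rows)
  if (n_extra > 0 && length(candidates) > 0) {
    pick <- sample(candidates, min(n_extra, length(candidates)))
    state$mrnas$class[pick] <- "inactive_granule"
  }
  state
}

#' Census of ribosomal species in a cell state
#'
#' Counts n-somes over active mRNAs (the harringtonine-stalled start-codon
#' 80S counts toward its mRNA's n), the granule n-some histogram, free 80S
#' and free subunits. The integer conservation identity
#' `sum(n * count) + sum(n * granule_count) + free_80S + subunits/2 = total`
#' holds exactly for every treatment except RNase1 (which only destroys).
#'
#' @param state A `cell_state`.
#' @return A list of class `"species_counts"`: `nsome` (tibble `n`, `count`
#'   over active mRNAs), `granule_nsome`, `free_80S`, `subunits`,
#'   `granule_ribosomes`, `total_80S_equivalents`.
#' @export
census <- function(state) {
  per_mrna <- rep(0L, nrow(state$mrnas))
  if (nrow(state$ribosomes) > 0 && nrow(state$mrnas) > 0) {
    tab <- tabulate(state$ribosomes$mrna, nbins = max(state$mrnas$mrna))
    per_mrna <- tab[state$mrnas$mrna]
  }
  n_tot <- per_mrna + state$mrnas$stalled
  act <- state$mrnas$class == "active" & n_tot > 0
  gran <- state$mrnas$class == "inactive_granule" & n_tot > 0
  hist_of <- function(v) {
    if (length(v) == 0) return(tibble(n = integer(0), count = integer(0)))
    tb <- table(v)
    tibble(n = as.integer(names(tb)), count = as.integer(tb))
  }
  out <- list(
    nsome = hist_of(n_tot[act]),
    granule_nsome = hist_of(n_tot[gran]),
    free_80S = state$free_80S,
    subunits = state$free_subunits,
    granule_ribosomes = sum(n_tot[gran]),
    total_80S_equivalents = sum(n_tot) + state$free_80S + state$free_subunits / 2
  )
  class(out) <- "species_counts"
  out
}

#' @export
print.species_counts <- function(x, ...) {
  cat(sprintf("<species_counts> %d active n-some classes | %d granule ribosomes | %d free 80S | %d subunits\n",
              nrow(x$nsome), x$granule_ribosomes, x$free_80S, x$subunits))
  invisible(x)
}

#' Ribosomes residing in polysomes (n >= 2), active plus granules
#'
#' @param counts A [census()] result.
#' @return Integer ribosome count.
#' @export
polysome_ribosomes <- function(counts) {
  a <- counts$nsome
  g <- counts$granule_nsome
  sum(a$n[a$n >= 2] * a$count[a$n >= 2]) + sum(g$n[g$n >= 2] * g$count[g$n >= 2])
}

#' Conservation check for the simulator
#'
#' @param state A `cell_state`.
#' @return TRUE iff the census total equals the state's recorded conserved
#'   80S-equivalent total exactly.
#' @export
conservation_holds <- function(state) {
  isTRUE(all.equal(census(state)$total_80S_equivalents,
                   state$total_ribosomes, tolerance = 0))
}
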