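# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# A small mixed-array consortium with planted isolated effects and one
# adjacent probe block, reused across module tests.
tiny_consortium <- function() {
  if (is.null(.fixture_env$tiny)) {
    cfg <- sim_config(n_cohorts = 4, n_samples = c(150, 200, 250, 300),
                      case_prevalence = c(0.2, 0.3, 0.4, 0.5),
                      array = c("450K", "450K", "EPIC", "EPIC"),
                      n_probes_shared = 300, n_probes_epic_only = 60,
                      n_causal = 3, effect_size_d = 0.5,
                      n_dmr_blocks = 1, dmr_block_size = 3,
                      dmr_block_d = 0.4, seed = 42)
    sim <- simulate_consortium(cfg)
    stats <- lapply(sim$cohorts, run_probe_regression, model = "ahrr")
    .fixture_env$tiny <- list(cfg = cfg, sim = sim, stats = stats,
                              meta = two_stage_meta(stats))
  }
  .fixture_env$tiny
}

# Fabricated summary-statistics table with full column contract.
fake_stats <- function(probes, betas, ses = 0.1, n = 100, study_id = "s1",
                       array = "450K", chr = "1",
                       pos = seq_along(probes) * 1000L,
                       p = NULL) {
  ses <- rep_len(ses, length(probes))
  if (is.null(p)) p <- 2 * pnorm(-abs(betas / ses))
  out <- data.frame(probe = probes, chr = chr, pos = pos, beta = betas,
                    se = ses, p = p, n = n, n_case = round(n / 2),
                    n_control = n - round(n / 2), study_id = study_id,
                    array = array, model = "ahrr",
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

permissive_config <- function()
  meta_config(presence_fraction = 1e-9, n_fraction_of_max = 1e-9)
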