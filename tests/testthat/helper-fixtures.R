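# Shared fixtures, all built in code.

# small deterministic expression matrix
tiny_matrix <- function(n_genes = 3, n_samples = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(round(rnorm(n_genes * n_samples, 7, 1), 4),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# metadata for a bare single-study design
tiny_metadata <- function(n = 6, ages = rep(c(3, 8), length.out = n)) {
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             study_id = "studyA",
             age_months = ages,
             exposure_group = "sham",
             exposure_months = ages - 2,
             stringsAsFactors = FALSE)
}

# two-arm, two-timepoint simulation small enough for fast loops
fast_sim_config <- function(seed = 1, ...) {
  designs <- list(list(
    study_id = "s1",
    design = expand.grid(arm = c("sham", "cs"),
                         timepoint = c(1, 6), n = 5,
                         stringsAsFactors = FALSE)))
  args <- modifyList(
    list(n_genes = 400, n_age_genes = 60, n_exposure_genes = 60,
         overlap_fraction = 0.5, study_designs = designs, batch_sd = 0,
         seed = seed),
    list(...))
  do.call(sim_config, args)
}

# reduced-size paper-like preset for loops where the full 2000-gene
# preset would be slow; identical study structure
small_paper_config <- function(seed = 1, ...) {
  paper_like_config(seed = seed, n_genes = 600, n_age_genes = 90,
                    n_exposure_genes = 90, ...)
}

expect_setequal_chr <- function(a, b) {
  expect_true(setequal(a, b),
              info = sprintf("sets differ: %d vs %d elements, %d shared",
                             length(a), length(b),
                             length(intersect(a, b))))
}
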