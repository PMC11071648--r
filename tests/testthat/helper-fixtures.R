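# Shared small fixtures, built in code at test time.

tinySurface <- function(subdiv = 1L, radius = 100) makeMesh(subdiv, radius)

# A bare BoldRun with iid noise data, for transform-level tests.
toyRun <- function(t = 40L, v = 10L, tr = 0.645, seed = 1L, data = NULL) {
  set.seed(seed)
  if (is.null(data)) data <- matrix(rnorm(t * v), nrow = t)
  new("BoldRun", subjectId = "toy", data = data, tr = tr,
      motion = matrix(rnorm(nrow(data) * 6, sd = 0.01), ncol = 6),
      tissue = matrix(rnorm(nrow(data) * 2), ncol = 2),
      generative = list(), provenance = character(0))
}

# Manual SeedMapSet over v vertices.
toySeeds <- function(weights, names = paste0("seed", seq_len(nrow(weights))))
  new("SeedMapSet", weights = weights, seedNames = names)

# Cohort with uniformly spread ages, balanced sexes.
toyCohort <- function(n = 40L, seed = 1L) {
  set.seed(seed)
  new("Cohort", table = data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    age = seq(8, 83, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    stringsAsFactors = FALSE))
}
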