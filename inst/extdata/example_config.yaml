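# Example run configuration for the conformity package.
# Omitted fields take package defaults; unknown keys are rejected.

simulation:
  n_subpop: 20        # number of subpopulations
  subpop_size: 50     # individuals per subpopulation (even; half each sex)
  beta: 2.8           # conformity strength of C females (beta > 1: conformist)
  d: 0.02             # dispersal fraction per generation
  r: 0.2              # recombination rate between trait and preference loci
  q0: 0.2             # initial frequency of the conformity allele C
  alpha: 0.0          # choice error rate of C females
  generations: 500
  perception: male-frequency   # or mating-observation
  seed: 1

sweep:
  betas: [1.0, 2.8]   # conformity strengths to sweep
  ds: [0.02, 0.8]     # dispersal fractions to sweep
  replicates: 20      # simulation runs per (beta, d) cell
  base_seed: 1

estimator:
  weighting: binomial # or ols
  unanimity: correct  # or drop

output_dir: "."
log_level: info
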