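# Example pipeline configuration for photothermal::run_pipeline() /
# `photothermal run --config example_run.yaml`.
# Keys mirror the arguments of run_config(); omitted keys use defaults.

out_dir: results/example        # artifacts + report.md land here
seed: 42                        # master seed for every stochastic stage

stages:                         # any subset of the five stages
  - simulate                    # synthetic 7-genotype growth-tent design
  - fit                         # variant comparison + classification
  - contrasts                   # 16v20 and 20v22 t-tests per genotype
  - qpcr                        # delta-Ct relative expression + tests
  - energy                      # lighting energy/cost ledger

# phenotypes_path: my_data.csv  # set to analyse real data instead of
                                # simulating (schema: see read_phenotypes)

replicates: 5                   # plants per genotype x photoperiod x run
repetitions: 2                  # experiment repetitions

variants:                       # model variants to fit and rank (BIC)
  - full
  - shared_T
  - flat

contrast_pairs:                 # photoperiod pairs for the t-tests (h)
  - [16, 20]
  - [20, 22]

reference_gene: HvTubA          # qPCR reference gene

energy_baseline_h: 22           # current speed-breeding photoperiod
energy_reduced_h: [20, 16]      # tailored photoperiods to cost out
facility_area_sqft: 10000       # for facility-level cost scaling
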