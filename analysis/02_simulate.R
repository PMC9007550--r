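#!/usr/bin/env Rscript
# Simulate the study-scale dataset: 740 participants (300 barworkers, 440
# porters) x 12 tasks x 3 alternatives, under a 2-class model with one
# privacy-domain random effect. Exports the long choice table, the
# participant covariates and the generating ground truth.

library(relcl)
dir.create("results", showWarnings = FALSE)

sch <- default_scheme()
design <- read_design("results/design.csv", sch)
truth <- example_params(sch, X = 2, D = 1)

set.seed(20250902)
ds <- simulate_dataset(sch, design, truth, n = 740)
print(ds)

write_choice_data(ds, "results/choices.csv", "results/participants.csv",
                  "results/truth.json", scheme = sch)
stopifnot(n_rankings(ds) == 8880, n_choice_records(ds) == 17760)
cat("8880 rankings / 17760 exploded choice records written\n")
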