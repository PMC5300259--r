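# Shared setup for the analysis scripts: fixture models, cohort designs and
# output locations. Each numbered script is a thin driver over the package;
# all computation lives in R/.

library(nmdarfx)

SEED <- 20170201L
RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

# calibrated receptor models, one per composition
MODELS <- list(
  WT2A          = read_kinetic_model(model_fixture("wt2A")),
  `2A-D731N`    = read_kinetic_model(model_fixture("d731n")),
  `2A/2A`       = read_kinetic_model(model_fixture("wt2A2A")),
  `D731N/2A`    = read_kinetic_model(model_fixture("d731n_2a")),
  `D731N/D731N` = read_kinetic_model(model_fixture("d731n_d731n"))
)

# group sizes follow the published cohort sizes for the matching experiment
N_CR <- c(WT2A = 7, `2A-D731N` = 11, `2A/2A` = 10, `D731N/2A` = 16,
          `D731N/D731N` = 11)
N_PULSE <- c(WT2A = 12, `2A-D731N` = 11)
N_MK <- c(WT2A = 8, `2A-D731N` = 10, `2A/2A` = 8, `D731N/2A` = 8,
          `D731N/D731N` = 17)

# between-cell variability: shared kinetic tempo (rescales time constants),
# small per-rate jitter (perturbs equilibrium quantities), expression spread
CV_JITTER <- 0.05
CV_TEMPO <- 0.4
CV_CHANNELS <- 0.6

# glutamate concentration series (uM): saturable for wild-type-potency
# receptors, truncated at 30 mM for the low-potency mutants
CR_CONCS <- list(
  WT2A          = c(0.3, 1, 3, 10, 30, 100),
  `2A-D731N`    = c(100, 300, 1000, 3000, 10000, 30000),
  `2A/2A`       = c(0.5, 1.5, 5, 15, 50, 150),
  `D731N/2A`    = c(50, 150, 500, 1500, 5000, 15000, 30000),
  `D731N/D731N` = c(300, 1000, 3000, 10000, 30000)
)
CR_MAX_MODE <- c(WT2A = "fix_to_observed", `2A-D731N` = "free_predicted",
                 `2A/2A` = "fix_to_observed", `D731N/2A` = "free_predicted",
                 `D731N/D731N` = "free_predicted")

# per-composition glutamate EC50 used to activate receptors in the MK-801
# and MTSEA experiments (the study-design convention)
EC50_GLU <- vapply(MODELS, apparent_ec50, numeric(1), axis = "glutamate")

oocyte_of <- function(comp) cell_meta(comp, "oocyte", comp)
hek_of <- function(comp) cell_meta(comp, "HEK", comp, capacitance = 20,
                                   holding_potential_default = -60)
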