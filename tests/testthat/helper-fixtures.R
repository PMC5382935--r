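# Shared simulated fixtures, built lazily and cached for the whole test run.
# Every cohort is fully seeded, so expectations are reproducible.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) assign(name, builder(), envir = .fx)
  .fx[[name]]
}

training_scenarios <- function() {
  list(sim_scenario(120, "EUPLOID"),
       sim_scenario(12, subject = "ADULT_MALE"),
       sim_scenario(12, subject = "ADULT_FEMALE"))
}

roles_from_truth <- function(truth) {
  data.frame(sample_id = truth$sample_id,
             role = ifelse(truth$subject == "PREGNANT", "PREGNANT",
                           truth$subject),
             stringsAsFactors = FALSE)
}

std_training <- function() {
  fixture("std_training", function() {
    simulate_cohort(training_scenarios(), sim_config(), seed = 101)
  })
}

std_ref <- function() {
  fixture("std_ref", function() {
    train <- std_training()
    train_nips(train$counts, train$bins, roles_from_truth(train$truth),
               nips_config(), regions = toy_regions())
  })
}

# The seeded separation cohort: 100 euploid + 20 T21 + 10 T18 + 10 T13
# singletons at FF ~ U(0.08, 0.15), default depth/dispersion.
separation_scenarios <- function() {
  list(sim_scenario(100, "EUPLOID"),
       sim_scenario(20, "T21"),
       sim_scenario(10, "T18"),
       sim_scenario(10, "T13"))
}

sep_cohort <- function() {
  fixture("sep_cohort", function() {
    simulate_cohort(separation_scenarios(), sim_config(), seed = 202)
  })
}

sep_results <- function() {
  fixture("sep_results", function() call_cohort(sep_cohort()$counts, std_ref()))
}

sex_cohort <- function() {
  fixture("sex_cohort", function() {
    simulate_cohort(list(
      sim_scenario(30, sex = "XX", ff = c(0.08, 0.20)),
      sim_scenario(30, sex = "XY", ff = c(0.08, 0.20)),
      sim_scenario(10, sex = "X", ff = c(0.08, 0.20)),
      sim_scenario(10, sex = "XXX", ff = c(0.08, 0.20)),
      sim_scenario(10, sex = "XXY", ff = c(0.08, 0.20)),
      sim_scenario(10, sex = "XYY", ff = c(0.08, 0.20))
    ), sim_config(), seed = 303)
  })
}

sex_results <- function() {
  fixture("sex_results", function() call_cohort(sex_cohort()$counts, std_ref()))
}

# Maternal events plus mosaic trisomy inside a mostly-euploid cohort.
event_cohort <- function() {
  fixture("event_cohort", function() {
    simulate_cohort(list(
      sim_scenario(40, "EUPLOID"),
      sim_scenario(4, "EUPLOID", maternal_dup = "21:0.45-0.55:3"),
      sim_scenario(4, "EUPLOID",
                   global_ab = "3:0.9;9:0.9;21:0.9;4:-0.9;6:-0.9;11:-0.9"),
      sim_scenario(6, "T21", ff = 0.10, mosaic = 0.25),
      sim_scenario(4, "EUPLOID", fetal_cnv = "22:0.40-0.60:1", ff = 0.15)
    ), sim_config(), seed = 404)
  })
}

event_results <- function() {
  fixture("event_results", function() call_cohort(event_cohort()$counts, std_ref()))
}

# Strong per-sample GC bias cohorts for the correction-rescue scenario.
gc_config <- function() sim_config(gc_bias_sd = 1.2)

gc_ref <- function() {
  fixture("gc_ref", function() {
    train <- simulate_cohort(training_scenarios(), gc_config(), seed = 111)
    train_nips(train$counts, train$bins, roles_from_truth(train$truth),
               nips_config())
  })
}

gc_rescue <- function() {
  fixture("gc_rescue", function() {
    ref <- gc_ref()
    train <- simulate_cohort(training_scenarios(), gc_config(), seed = 111)
    coh <- simulate_cohort(list(sim_scenario(40, "EUPLOID"),
                                sim_scenario(8, "T13", ff = 0.10)),
                           gc_config(), seed = 222)
    preg <- train$truth$subject == "PREGNANT"
    train_preg <- count_matrix(train$counts$counts[preg, , drop = FALSE],
                               train$counts$samples[preg, , drop = FALSE])
    ref_raw <- fit_chrom_reference(
      scale_by_autosomal_total(train_preg, ref$bins), ref$bins)
    z_raw <- cohort_zscores(scale_by_autosomal_total(coh$counts, ref$bins),
                            ref$bins, ref_raw)
    list(cohort = coh, z_raw = z_raw,
         results = call_cohort(coh$counts, ref))
  })
}

# Cohorts with a planted fetal-fraction-correlated autosomal signal for the
# female-fetus regression (same pattern seed in training and held-out).
ff_signal_ref <- function() {
  fixture("ff_signal_ref", function() {
    train <- simulate_cohort(list(
      sim_scenario(150, "EUPLOID", sex = "XY", ff = c(0.04, 0.25)),
      sim_scenario(20, "EUPLOID", sex = "XX"),
      sim_scenario(12, subject = "ADULT_MALE"),
      sim_scenario(12, subject = "ADULT_FEMALE")
    ), sim_config(), seed = 505)
    train <- plant_female_ff_signal(train, strength = 0.85, seed = 99)
    train_nips(train$counts, train$bins, roles_from_truth(train$truth),
               nips_config())
  })
}

ff_signal_holdout <- function() {
  fixture("ff_signal_holdout", function() {
    coh <- simulate_cohort(list(
      sim_scenario(60, "EUPLOID", sex = "XY", ff = c(0.04, 0.25))
    ), sim_config(), seed = 606)
    plant_female_ff_signal(coh, strength = 0.85, seed = 99)
  })
}

# thin wrapper over the internal normalized-matrix constructor
new_nm_for_test <- function(vals, stage) {
  cfnips:::new_normalized(vals,
                          data.frame(sample_id = rownames(vals), plate = "P1",
                                     stringsAsFactors = FALSE),
                          stage)
}
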