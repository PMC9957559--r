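# The published benchmark designs the acceptance suite replicates: each row
# is a search-selected sequential design together with its reported power
# (and, where applicable, reported type I error) at R = 1000 replicates.

target_designs <- function() {
  list(
    t1 = list(design = bernoulli_dip_design(0.1, 22, 0.98, 0.02),
              theta1 = 0.30, power = 0.801, type1_printed = 0.050),
    t2 = list(design = bernoulli_dip_design(0.1, 76, 0.98, 0.10),
              theta1 = 0.20, power = 0.802, type1_printed = 0.050),
    t4 = list(design = bernoulli_dip_design(0.1, 42, 0.98, 0.06),
              theta1 = 0.25, power = 0.843, type1_printed = 0.050),
    t5 = list(design = bernoulli_flat_design(0.1, 88, 0.99, 0.02),
              theta1 = 0.20, power = 0.868, type1_printed = 0.076),
    t6 = list(design = poisson_dip_design(5, 10, 0.95, 0.03),
              theta1 = 3, power = 0.945, type1_printed = 0.050),
    t7 = list(design = poisson_dip_design(0.5, 68, 0.98, 0.07),
              theta1 = 0.3, power = 0.806, type1_printed = 0.050),
    t8 = list(design = normal_dip_design(100, 15, 61, 0.98, 0.07),
              theta1 = 95, power = 0.802, type1_printed = 0.050),
    t9 = list(design = normal_dip_design(100, 30, 60, 0.97, 0.05),
              theta1 = 90, power = 0.811, type1_printed = 0.050)
  )
}
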