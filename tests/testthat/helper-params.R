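# shared fixtures, built in code

# male final-model estimates
male_params <- function() {
  pk_parameters(V1 = 17.5, kel = 3.60, k12 = 2.14, k21 = 2.62,
                k13 = 17.6, k31 = 39.6, k14 = 9.37, k41 = 71.0,
                k15 = 0.081, k51 = 6.84, k35 = 0.928, k53 = 66.6,
                kPgp = 81.9, V1_TRQ = 12.7, kel_TRQ = 3.38,
                kPgp_TRQ = 0.0021)
}

male_dose <- function() dose_from_weight(10, default_body_weight("M"))

# random positive parameter set for property-style loops
random_params <- function() {
  r <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  pk_parameters(V1 = r(5, 50), kel = r(0.5, 10), k12 = r(0.1, 10),
                k21 = r(0.1, 10), k13 = r(1, 50), k31 = r(1, 100),
                k14 = r(1, 50), k41 = r(1, 100), k15 = r(0.01, 1),
                k51 = r(1, 50), k35 = r(0.1, 5), k53 = r(5, 100),
                kPgp = r(1, 150), kPgp_TRQ = r(1e-4, 1e-2))
}

# a tiny valid dataset for io tests
tiny_dataset <- function() {
  data.frame(group = c("WT", "WT", "KO", "OT"),
             sex = "M",
             matrix = c("plasma", "brain", "plasma", "plasma"),
             time = c(0.5, 0.5, 0.5, 1),
             mean_conc = c(10, 2, 11, 12),
             sd = c(1, 0.2, 1.2, 1.5),
             n = c(5L, 5L, 5L, 4L),
             censored = FALSE,
             stringsAsFactors = FALSE)
}
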