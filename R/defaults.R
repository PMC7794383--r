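#' Default generating process calibrated to the 1982 Pelotas women's data
#'
#' Returns a [generation_config()] whose marginal structure matches the
#' published characteristics of the cohort at the 30-year visit: category
#' probabilities for family income, maternal schooling, breastfeeding
#' duration and birthweight; African genomic-ancestry proportion as a Beta
#' variable (mean 0.16, SD 0.19); exposure probabilities (0.245, 0.535,
#' 0.220) for menarche before 12, at 12-13 and at 14+ years.  The mediator
#' models (BMI, fat mass index, waist-to-hip ratio x100) use the published
#' confounder-adjusted exposure coefficients as true effects, and the
#' outcome models are calibrated so that the implied natural direct and
#' indirect effects for diastolic blood pressure through fat mass index are
#' 0.58 and 1.07 mmHg respectively.  In this generating process fat mass
#' index is the single true mediator of every outcome; BMI and
#' waist-to-hip ratio are correlated body-composition measures so that
#' analyses using them as the working mediator are structurally valid but
#' deliberately misspecified with respect to the truth.
#'
#' These values are calibration targets describing the emulated population,
#' not assertions about causal truth in the real cohort.
#'
#' @param n number of rows (default 1680, the analysed sample size).
#' @param seed default generation seed.
#' @return a `generation_config`.
#' @export
default_generation_config <- function(n = 1680, seed = NULL) {
  confounder_specs <- list(
    family_income_cat = list(
      type = "categorical",
      levels = c("lt1", "1to3", "3to6", "6to10", "gt10"),
      probs = c(0.196, 0.511, 0.186, 0.056, 0.051)),
    household_score = list(type = "normal", mean = 3.32, sd = 1.20),
    maternal_schooling_cat = list(
      type = "categorical",
      levels = c("0to4", "5to8", "9to11", "ge12"),
      probs = c(0.332, 0.423, 0.110, 0.135)),
    maternal_smoking = list(type = "binary", p = 0.351),
    birthweight_g = list(type = "normal", mean = 3200, sd = 510,
                         lower = 1000, upper = 5500),
    breastfeeding_cat = list(
      type = "categorical",
      levels = c("lt1", "1to3", "3to6", "6to9", "9to12", "ge12"),
      probs = c(0.197, 0.267, 0.234, 0.094, 0.037, 0.172) /
        sum(c(0.197, 0.267, 0.234, 0.094, 0.037, 0.172))),
    african_ancestry = list(type = "beta", mean = 0.16, sd = 0.19)
  )

  alpha_L <- list(
    # leisure-time + commuting physical activity >= 150 min/week
    active = list(type = "binary", a0 = -1.42,
                  a1 = c(lt12 = -0.20, mid = -0.05),
                  a2 = c(household_score = 0.05)),
    saturated_fat_pct = list(type = "continuous", a0 = 9.85,
                             a1 = c(lt12 = 0.10, mid = 0.05),
                             a2 = c(household_score = 0.07), sd = 2.60)
  )

  beta <- list(
    bmi = list(b0 = 25.2, b1 = c(lt12 = 3.58, mid = 0.60),
               b2 = c(household_score = -0.20, african_ancestry = 0.80),
               bL = c(active = -0.80, saturated_fat_pct = 0.05),
               sd = 4.8, lower = 0.1),
    fat_mass_index = list(b0 = 9.9, b1 = c(lt12 = 2.84, mid = 0.51),
                          b2 = c(household_score = -0.15,
                                 african_ancestry = 0.50),
                          bL = c(active = -0.70, saturated_fat_pct = 0.04),
                          sd = 4.4, lower = 0.1),
    waist_hip_ratio = list(b0 = 74.8, b1 = c(lt12 = 1.97, mid = 0.98),
                           b2 = c(household_score = -0.10,
                                  african_ancestry = 1.00),
                           bL = c(active = -0.50,
                                  saturated_fat_pct = 0.03),
                           sd = 6.3)
  )

  # E[fat_mass_index | A = ge14] is about 9.75 under these parameters;
  # theta for dbp is solved so that NDE = t1 + tam * 9.75 = 0.58 and
  # NIE = (tm + tam) * 2.84 = 1.07 for the lt12 vs ge14 contrast.
  theta <- list(
    sbp = list(t0 = 109.5, t1 = c(lt12 = -0.10, mid = -0.30),
               tm = c(fat_mass_index = 0.35),
               tam = list(fat_mass_index = c(lt12 = 0.02, mid = 0.01)),
               t4 = c(household_score = 0.30, african_ancestry = 2.00),
               tL = c(active = -0.50, saturated_fat_pct = 0.10), sd = 11.0),
    dbp = list(t0 = 70.0, t1 = c(lt12 = 0.29, mid = 0.20),
               tm = c(fat_mass_index = 0.35),
               tam = list(fat_mass_index = c(lt12 = 0.03)),
               t4 = c(household_score = 0.20, african_ancestry = 1.50),
               tL = c(active = -0.40, saturated_fat_pct = 0.05), sd = 8.8),
    total_chol = list(t0 = 172, t1 = c(lt12 = 2.55, mid = 1.00),
                      tm = c(fat_mass_index = 0.80),
                      tam = list(fat_mass_index = c(lt12 = 0.06)),
                      t4 = c(household_score = 0.50),
                      tL = c(saturated_fat_pct = 0.40), sd = 34),
    hdl = list(t0 = 66, t1 = c(lt12 = 1.16, mid = 0.45),
               tm = c(fat_mass_index = -0.20),
               t4 = c(household_score = 0.10),
               tL = c(active = 0.50), sd = 13.5),
    ldl = list(t0 = 92, t1 = c(lt12 = -0.94, mid = 0.50),
               tm = c(fat_mass_index = 1.217),
               tam = list(fat_mass_index = c(lt12 = 0.10)),
               t4 = c(household_score = 0.40),
               tL = c(saturated_fat_pct = 0.30), sd = 27),
    triglycerides = list(t0 = 4.35, t1 = c(lt12 = 0.0103, mid = 0.005),
                         tm = c(fat_mass_index = 0.0096),
                         tam = list(fat_mass_index = c(lt12 = 0.001)),
                         t4 = c(household_score = 0.01),
                         tL = c(saturated_fat_pct = 0.005), sd = 0.62),
    glucose = list(t0 = 82, t1 = c(lt12 = 0.50, mid = 0.20),
                   tm = c(fat_mass_index = 0.30),
                   tL = c(active = -0.40), sd = 20),
    hba1c = list(t0 = 4.85, t1 = c(lt12 = 0.01, mid = 0.005),
                 tm = c(fat_mass_index = 0.02), sd = 0.50),
    crp = list(t0 = -0.65, t1 = c(lt12 = -0.09, mid = -0.02),
               tm = c(fat_mass_index = 0.067),
               t4 = c(african_ancestry = 0.10),
               tL = c(active = -0.05), sd = 1.00),
    cimt = list(t0 = 572, t1 = c(lt12 = 0.50, mid = 0.20),
                tm = c(fat_mass_index = 0.50),
                t4 = c(household_score = 0.50), sd = 15.9),
    pwv = list(t0 = 6.20, t1 = c(lt12 = 0.05, mid = 0.02),
               tm = c(fat_mass_index = 0.012),
               tL = c(active = -0.05), sd = 1.05)
  )

  generation_config(
    n = n,
    exposure_probs = c(0.245, 0.535, 0.220),
    confounder_specs = confounder_specs,
    alpha_L = alpha_L,
    beta = beta,
    theta = theta,
    log_scale_outcomes = c("triglycerides", "crp"),
    exclusion_rates = list(pregnant = 0.015, postpartum_3m = 0.012,
                           oral_contraceptive = 0.25, missing = 0),
    seed = seed
  )
}
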