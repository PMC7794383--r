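# Slim generating processes used across tests: one standard-normal
# confounder z, one mediator "med", one outcome "out", optional
# post-confounders (binary l1, continuous l2).

slim_config <- function(n = 2000, b0 = 2, b1 = 2, t0 = 1, t1 = 1,
                        tm = 0.5, tam = 0.2, sd_m = 1, sd_y = 1,
                        with_L = FALSE, b2 = c(z = 0.5), t4 = c(z = 0.4),
                        exposure_probs = c(0.3, 0.4, 0.3)) {
  generation_config(
    n = n,
    exposure_probs = exposure_probs,
    confounder_specs = list(z = list(type = "normal", mean = 0, sd = 1)),
    alpha_L = if (with_L) {
      list(l1 = list(type = "binary", a0 = -0.5, a1 = c(lt12 = 0.3),
                     a2 = c(z = 0.2)),
           l2 = list(type = "continuous", a0 = 1,
                     a1 = c(lt12 = 0.5, mid = 0.2), a2 = c(z = 0.3),
                     sd = 1))
    } else list(),
    beta = list(med = list(
      b0 = b0, b1 = c(lt12 = b1, mid = 0.3 * b1), b2 = b2,
      bL = if (with_L) c(l1 = 0.4, l2 = 0.3), sd = sd_m)),
    theta = list(out = list(
      t0 = t0, t1 = c(lt12 = t1, mid = 0.3 * t1), tm = c(med = tm),
      tam = if (tam != 0) list(med = c(lt12 = tam)),
      t4 = t4, tL = if (with_L) c(l1 = 0.5, l2 = 0.2), sd = sd_y))
  )
}

slim_spec <- function(with_L = FALSE, interaction = TRUE) {
  mediation_spec("med", "out", base_confounders = "z",
                 post_confounders = if (with_L) c("l1", "l2")
                                    else character(),
                 interaction = interaction)
}

# Independent brute-force Monte-Carlo oracle for the slim no-L process:
# simulates the generating equations directly (not via the package
# generator) and returns the counterfactual-mean contrasts.
mc_oracle_slim <- function(cfg, n_draws = 2e5) {
  b <- cfg$beta$med
  th <- cfg$theta$out
  tamv <- if (is.null(th$tam)) 0 else th$tam$med[["lt12"]]
  z <- rnorm(n_draws, 0, 1)
  m_at <- function(a) {
    b$b0 + (if (a == 1) b$b1[["lt12"]] else 0) + b$b2[["z"]] * z +
      rnorm(n_draws, 0, b$sd)
  }
  y_at <- function(a, m) {
    th$t0 + (if (a == 1) th$t1[["lt12"]] else 0) +
      (th$tm[["med"]] + (if (a == 1) tamv else 0)) * m +
      th$t4[["z"]] * z
  }
  m0 <- m_at(0); m1 <- m_at(1)
  d_nde <- y_at(1, m0) - y_at(0, m0)
  d_nie <- y_at(1, m1) - y_at(1, m0)
  list(nde = mean(d_nde), nie = mean(d_nie),
       se_nde = sd(d_nde) / sqrt(n_draws),
       se_nie = sd(d_nie) / sqrt(n_draws))
}

default_base_confounders <- c("family_income_cat", "household_score",
                              "maternal_schooling_cat", "maternal_smoking",
                              "birthweight_g", "breastfeeding_cat",
                              "african_ancestry")
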