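#' Reference constants from a cracker accelerated shelf-life study
#'
#' Published summary tables from a storage study of crackers baked with
#' sunflower oil at three oxidation levels (oil peroxide values of about 5,
#' 11 and 25 mEq O2/kg oil) and stored at 20, 40 and 60 degree C. The bundle
#' carries the fresh-product quality table, the per-temperature zero-order
#' rate constants of rancid-odor formation with their regression
#' diagnostics, the Arrhenius parameters per batch, and the coefficients of
#' the rate-versus-oil-PV line fitted at 20 degree C. These serve as
#' fixtures for the fitting chain and as inputs for the fixture mode of
#' [run_pipeline()].
#'
#' @return a list with elements
#' \describe{
#'   \item{oil_pv}{named numeric: peroxide values of the three ingredient
#'     oil batches, mEq O2/kg oil.}
#'   \item{fresh}{data frame of just-baked cracker measurements: cracker PV
#'     and rancid-odor intensity (mean and SD) per batch.}
#'   \item{rates}{data frame of zero-order rate constants: `batch_label`,
#'     `oil_pv`, `temperature_C`, `k` (intensity/day), `se_k`, `r2`.}
#'   \item{arrhenius}{data frame per batch: frequency factor `k0`
#'     (intensity/day), activation energy `Ea_kJ_mol`, `r2`, `p`.}
#'   \item{rate_vs_pv}{list: `slope`, `intercept`, `r2`, `temperature_C` of
#'     the published k-versus-PV line at 20 degree C.}
#'   \item{shelf_life}{list: default initial intensity `I0` (mean fresh
#'     rancid-odor score), default acceptability limit `I_lim`, and the PV
#'     validity range of the rate model.}
#' }
#' @export
cracker_fixtures <- function() {
  oil_pv <- c(low = 5.06, intermediate = 11.34, high = 25.22)

  fresh <- data.frame(
    batch_label = names(oil_pv),
    oil_pv = unname(oil_pv),
    cracker_pv = c(13.86, 18.18, 14.02),
    cracker_pv_sd = c(3.06, 1.48, 1.10),
    rancid_intensity = c(4.17, 4.10, 4.72),
    rancid_intensity_sd = c(1.08, 0.95, 0.90)
  )

  rates <- data.frame(
    batch_label = rep(names(oil_pv), each = 3L),
    oil_pv = rep(unname(oil_pv), each = 3L),
    temperature_C = rep(c(20, 40, 60), times = 3L),
    k = c(0.013, 0.040, 0.156,
          0.025, 0.067, 0.363,
          0.038, 0.136, 0.684),
    se_k = c(0.003, 0.003, 0.018,
             0.003, 0.003, 0.017,
             0.018, 0.017, 0.033),
    r2 = c(0.81, 0.98, 0.95,
           0.95, 0.99, 0.95,
           0.95, 0.95, 0.99)
  )

  arrhenius <- data.frame(
    batch_label = names(oil_pv),
    oil_pv = unname(oil_pv),
    k0 = c(1.37e7, 7.81e7, 2.48e8),
    Ea_kJ_mol = c(50.82, 53.53, 58.53),
    r2 = c(0.99, 0.96, 0.99),
    p = c(0.06, 0.12, 0.06)
  )

  list(
    oil_pv = oil_pv,
    fresh = fresh,
    rates = rates,
    arrhenius = arrhenius,
    rate_vs_pv = list(slope = 0.0012, intercept = 0.009, r2 = 0.99,
                      temperature_C = 20),
    shelf_life = list(I0 = round(mean(fresh$rancid_intensity), 2),
                      I_lim = 6, pv_valid_range = c(5, 25))
  )
}
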