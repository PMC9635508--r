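#' Reference Richards parameter estimates for four japonica cultivars
#'
#' Published per-series Richards parameter estimates (`A`, `B`, `K`, `N`,
#' plus the reported fit `R2`) for superior and inferior grains of four
#' japonica rice cultivars (Suijing-18, Longjing-21, Longdao-21, Longdao-18)
#' grown at two high-latitude sites in Heilongjiang, China (Harbin and
#' Qiqihar) in 2017 and 2018 — 32 series in all. These estimates define the
#' parameter regimes the synthetic-data generator emulates and serve as
#' worked examples for [filling_characteristics()].
#'
#' Four Qiqihar superior-grain series (Suijing-18 and Longjing-21, both
#' years) have `B <= N`, i.e. an analytic rate peak at or before the time
#' origin; [filling_characteristics()] flags them as
#' `"pre_anthesis_maximum"`.
#'
#' @return A tibble with columns `cultivar`, `grain_class`
#'   (`"superior"`/`"inferior"`), `site`, `year`, `A`, `B`, `K`, `N`, `R2`.
#' @examples
#' params <- richards_reference_params()
#' filling_characteristics(params[1, ])
#' @export
richards_reference_params <- function() {
  tab <- read.csv(text = "cultivar,grain_class,site,year,A,B,K,N,R2
Suijing-18,superior,Harbin,2017,22.91,13.79,0.24,0.55,0.999
Suijing-18,superior,Harbin,2018,22.70,13.57,0.24,0.55,0.998
Suijing-18,superior,Qiqihar,2017,22.76,0.81,0.60,1.52,0.998
Suijing-18,superior,Qiqihar,2018,23.01,0.85,0.63,1.57,0.999
Suijing-18,inferior,Harbin,2017,20.85,18.77,0.18,0.49,0.999
Suijing-18,inferior,Harbin,2018,20.51,18.91,0.19,0.51,0.998
Suijing-18,inferior,Qiqihar,2017,15.28,2.94,0.16,0.28,0.983
Suijing-18,inferior,Qiqihar,2018,15.51,3.13,0.18,0.31,0.987
Longjing-21,superior,Harbin,2017,24.03,20.24,0.24,0.66,0.999
Longjing-21,superior,Harbin,2018,23.87,20.47,0.27,0.69,0.998
Longjing-21,superior,Qiqihar,2017,22.31,1.70,1.28,3.20,0.994
Longjing-21,superior,Qiqihar,2018,22.62,1.87,1.37,3.31,0.998
Longjing-21,inferior,Harbin,2017,21.79,17.35,0.22,0.69,0.999
Longjing-21,inferior,Harbin,2018,21.50,17.14,0.21,0.65,0.994
Longjing-21,inferior,Qiqihar,2017,19.59,0.54,0.12,0.08,0.987
Longjing-21,inferior,Qiqihar,2018,20.01,0.61,0.14,0.10,0.989
Longdao-21,superior,Harbin,2017,23.78,9.01,0.25,0.60,0.998
Longdao-21,superior,Harbin,2018,23.57,8.89,0.24,0.59,0.988
Longdao-21,superior,Qiqihar,2017,21.97,1.89,0.21,0.25,0.997
Longdao-21,superior,Qiqihar,2018,22.14,1.96,0.25,0.27,0.999
Longdao-21,inferior,Harbin,2017,19.35,0.74,0.13,0.10,0.996
Longdao-21,inferior,Harbin,2018,19.07,0.66,0.12,0.08,0.993
Longdao-21,inferior,Qiqihar,2017,19.53,5.93,0.15,0.38,0.991
Longdao-21,inferior,Qiqihar,2018,19.87,6.27,0.16,0.38,0.995
Longdao-18,superior,Harbin,2017,22.36,15.84,0.26,0.69,0.999
Longdao-18,superior,Harbin,2018,22.11,15.63,0.24,0.63,0.989
Longdao-18,superior,Qiqihar,2017,20.88,0.60,0.14,0.11,0.993
Longdao-18,superior,Qiqihar,2018,21.10,0.88,0.17,0.13,0.997
Longdao-18,inferior,Harbin,2017,18.01,0.80,0.13,0.08,0.997
Longdao-18,inferior,Harbin,2018,17.92,0.79,0.11,0.07,0.995
Longdao-18,inferior,Qiqihar,2017,14.32,0.80,0.09,0.09,0.997
Longdao-18,inferior,Qiqihar,2018,14.69,0.91,0.10,0.10,0.999
", stringsAsFactors = FALSE)
  as_tibble(tab)
}

#' Grain-filling-stage environment summaries for the two study sites
#'
#' Mean environmental conditions during the grain-filling stage for each
#' cultivar, site and year of the reference field study: mean/maximum/minimum
#' air temperature (deg C), daily sunshine (h), solar radiation (MJ m^-2),
#' relative humidity (%), and soil temperature at 5 and 10 cm depth (deg C).
#' These per-site-year constants are the environment covariates available to
#' the synthetic trait generator; no daily weather series is modelled.
#'
#' @return A tibble with columns `cultivar`, `site`, `year`, `T_avg`,
#'   `T_max_env`, `T_min`, `sunshine_h`, `radiation_MJ_m2`, `RH_pct`,
#'   `soil_temp_5cm`, `soil_temp_10cm`.
#' @examples
#' site_environment()
#' @export
site_environment <- function() {
  tab <- read.csv(text = "cultivar,site,year,T_avg,T_max_env,T_min,sunshine_h,radiation_MJ_m2,RH_pct,soil_temp_5cm,soil_temp_10cm
Suijing-18,Harbin,2017,20.26,26.01,15.00,6.24,17.64,82.81,21.73,20.32
Suijing-18,Harbin,2018,19.21,25.34,14.32,6.54,17.93,80.13,22.24,20.97
Suijing-18,Qiqihar,2017,18.44,24.38,12.96,7.30,16.72,80.99,19.77,18.23
Suijing-18,Qiqihar,2018,19.67,25.14,13.45,7.41,16.98,78.16,21.05,20.53
Longjing-21,Harbin,2017,20.41,26.10,15.19,6.25,17.71,82.73,21.87,20.45
Longjing-21,Harbin,2018,21.77,27.18,16.23,6.11,17.93,80.43,22.78,21.04
Longjing-21,Qiqihar,2017,18.62,24.44,13.26,7.16,16.66,81.44,19.91,18.37
Longjing-21,Qiqihar,2018,18.93,25.67,14.54,6.98,16.34,79.12,20.45,19.13
Longdao-21,Harbin,2017,19.97,25.68,14.80,5.75,16.81,83.36,21.24,19.84
Longdao-21,Harbin,2018,20.90,26.81,15.61,6.61,16.09,81.90,21.78,20.12
Longdao-21,Qiqihar,2017,16.91,22.95,11.15,7.74,16.81,77.38,18.66,17.11
Longdao-21,Qiqihar,2018,17.54,23.76,13.01,7.11,17.11,79.14,20.07,18.96
Longdao-18,Harbin,2017,20.15,25.92,14.99,5.88,17.09,83.32,21.48,20.06
Longdao-18,Harbin,2018,21.43,26.12,16.73,6.13,17.56,81.45,22.11,19.76
Longdao-18,Qiqihar,2017,17.71,23.69,12.05,7.31,16.58,79.77,19.27,17.72
Longdao-18,Qiqihar,2018,18.32,24.53,14.08,7.79,17.18,80.67,21.03,19.07
", stringsAsFactors = FALSE)
  as_tibble(tab)
}
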