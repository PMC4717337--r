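# Physical constants and air properties used across the models.

SIGMA_SB <- 5.670374e-8   # Stefan-Boltzmann, W/(m^2 K^4)
SOLAR_CONSTANT <- 1361    # W/m^2
ENERGY_PER_ML_O2 <- 20.1  # J per mL O2 consumed
LATENT_HEAT_VAP <- 2.4e6  # J/kg water (2.4 kJ/g)
O2_FRACTION_AIR <- 0.2095
R_GAS <- 8.31446          # J/(mol K)
MW_WATER <- 0.018         # kg/mol

c_to_k <- function(t) t + 273.15

# Saturation vapour pressure (Pa), Tetens over water.
saturation_vapour_pressure <- function(t_c) {
  610.78 * exp(17.27 * t_c / (t_c + 237.3))
}

# Absolute humidity (kg/m^3) at temperature t_c and relative humidity rh (%).
vapour_density <- function(t_c, rh = 100) {
  e <- saturation_vapour_pressure(t_c) * rh / 100
  e * MW_WATER / (R_GAS * c_to_k(t_c))
}

# Air thermal conductivity (W/m K) and kinematic viscosity (m^2/s),
# linear fits adequate for -40..60 C.
air_conductivity <- function(t_c) 0.02425 + 7.0e-5 * t_c
air_kinematic_viscosity <- function(t_c) 1.33e-5 + 9.0e-8 * t_c
AIR_PRANDTL <- 0.71

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite <- function(x, name = deparse(substitute(x))) {
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  }
  invisible(x)
}
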