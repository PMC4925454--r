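# Frozen reference values computed with an independent arbitrary-precision
# implementation (40 significant digits) of the analytic solution: the basis
# function via erfi, the coefficient linear solve, Gauss-Legendre quadrature
# for the shell integrals, and the backward-equation double quadrature.

oracle_f <- c(
  "0.1" = -9.9003326676179904,
  "1"   = -0.27522154099292367,
  "2"   =  0.13998807456540893,
  "5"   =  0.0092457571954755571,
  "50"  =  8.0096192539543920e-6,
  "100" =  1.0003001501050946e-6
)
oracle_f_sqrt3 <- 0.13222698635441786

# coefficients for a_bar = 1, R_bar = sqrt(3)
oracle_A_inner <- 1.9435184130840573
oracle_B_inner <- 4.2831077138756096

# shell integrals on [1, sqrt(3)]
oracle_delta1 <- 0.51339103518675430
oracle_delta2 <- 1.0434919900174840

# scaled mean capture time tau/tau0 at a = b for selected N
oracle_tau <- c(
  "2"     = 0.2495385675542613,
  "3"     = 0.75162353659164807,
  "5"     = 2.076787250666061,
  "10"    = 6.746511740776979,
  "100"   = 238.9493323723906,
  "1000"  = 7628.237901496724,
  "10000" = 241285.2863488852
)

# dose-response curve at the reference parameters
oracle_dm454 <- 10.206168534747137

# convenience: random rate sets drawn reproducibly for property tests
random_rate_sets <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    r_on = stats::runif(n, 0.05, 5),
    r_off = stats::runif(n, 0.05, 5),
    r_off_double = stats::runif(n, 1e-4, 0.04),
    tau = stats::runif(n, 0, 3)
  )
}
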