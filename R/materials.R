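#' Elastic material set for the denture model
#'
#' Isotropic linear-elastic constants per material label. Defaults are the
#' two denture acrylics: base plastic E = 1000 MPa and tooth plastic
#' E = 2000 MPa, both with Poisson ratio 0.3 and density 1000 kg/m^3
#' (density is carried but unused in the static analysis). The ultimate
#' compressive strength of the base acrylic defaults to 60 MPa.
#'
#' @param E named numeric, Young's modulus in MPa per material label.
#' @param nu Poisson ratio(s); recycled over labels. Must satisfy
#'   `0 <= nu < 0.5`.
#' @param rho density(ies) in kg/m^3 (carried, unused).
#' @param sigma_uc ultimate compressive strength of the base material, MPa.
#' @return an object of class `material_set`.
#' @export
material_set <- function(E = c(base = 1000, tooth = 2000), nu = 0.3,
                         rho = 1000, sigma_uc = 60) {
  if (is.null(names(E)) || any(names(E) == ""))
    stop("E must be a named vector (one entry per material label)")
  if (any(E <= 0)) stop("Young's moduli must be positive")
  nu <- rep_len(nu, length(E))
  rho <- rep_len(rho, length(E))
  if (any(nu < 0 | nu >= 0.5))
    stop("Poisson ratio must satisfy 0 <= nu < 0.5")
  structure(list(E = E, nu = setNames(nu, names(E)),
                 rho = setNames(rho, names(E)), sigma_uc = sigma_uc),
            class = "material_set")
}

# 6x6 isotropic elasticity matrix, Voigt order (xx,yy,zz,xy,yz,zx),
# engineering shear strains
elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}
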