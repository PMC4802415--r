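#' Kinetic parameters of the Rac1-RhoA-PAK network
#'
#' Constructs and validates the full set of rate constants. Units follow
#' the nM/min convention: mass-action on-rates in 1/(nM min), first-order
#' rates and catalytic constants in 1/min, Michaelis constants in nM and
#' basal maximal rates (`Vb_*`, `V_*`) in nM/min.
#'
#' @param ... named kinetic constants; all 27 must be supplied (see
#'   [kinetics_names()]). Values must be finite and >= 0; every Michaelis
#'   constant (`Km_*`) must be strictly positive.
#' @return Named numeric vector of class `rr_kinetics`.
#' @export
kinetics <- function(...) {
  k <- c(...)
  validate_kinetics(k)
  structure(k[kinetics_names()], class = "rr_kinetics")
}

#' Canonical order of the kinetic constants
#'
#' @return Character vector of the 27 parameter names, in the order passed
#'   to the compiled right-hand side.
#' @export
kinetics_names <- function() {
  c("Vb_racgef", "Km_r1",
    "kcat_gap", "Vb_racgap", "Km_r2",
    "kcat_gef", "Vb_rhogef", "Km_r3",
    "Vb_rhogap", "Km_r4",
    "kon_pak", "koff_pak", "k_auto",
    "V_ppase", "Km_p",
    "kcat_pakgef", "Km_g",
    "V_gppase", "Km_gp",
    "kon_14", "koff_14",
    "kcat_rho", "Km_ga",
    "V_gapoff", "Km_gd",
    "kon_i", "koff_i")
}

validate_kinetics <- function(k) {
  need <- kinetics_names()
  missing <- setdiff(need, names(k))
  if (length(missing) > 0) {
    stop("missing kinetic constant(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  km <- grep("^Km_", need, value = TRUE)
  for (nm in need) {
    v <- k[[nm]]
    if (!is.finite(v)) stop("kinetic constant '", nm, "' is not finite",
                            call. = FALSE)
    if (v < 0) stop("kinetic constant '", nm, "' is negative", call. = FALSE)
    if (nm %in% km && v <= 0) {
      stop("Michaelis constant '", nm,
           "' must be > 0 where a Michaelis-Menten law is used",
           call. = FALSE)
    }
  }
  invisible(k)
}

as_kinetics <- function(x) {
  k <- unclass(x)[kinetics_names()]
  names(k) <- kinetics_names()
  validate_kinetics(k)
  structure(k, class = "rr_kinetics")
}

#' @export
print.rr_kinetics <- function(x, ...) {
  cat("Kinetic constants (nM, min units):\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}
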