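#' Total protein abundances of the conserved moieties
#'
#' Constructs and validates the vector of total concentrations (nM) of the
#' six conserved proteins: Rac1, RhoA, PAK, GEF-H1, 14-3-3 and the Rac GAP.
#' The first five are the quantities varied in abundance-space scans; the
#' Rac GAP total is a model-internal moiety lumping the RhoA-effector
#' (ROCK-activated) Rac GAPs into a single conserved pool.
#'
#' @param rac1_tot,rhoa_tot,pak_tot,gefh1_tot,s1433_tot,racgap_tot total
#'   concentrations in nM; each must be finite and >= 0.
#' @return Named numeric vector of class `rr_abundances`.
#' @export
#' @examples
#' abundances(rac1_tot = 400, rhoa_tot = 500, pak_tot = 600,
#'            gefh1_tot = 55, s1433_tot = 500, racgap_tot = 200)
abundances <- function(rac1_tot, rhoa_tot, pak_tot, gefh1_tot, s1433_tot,
                       racgap_tot) {
  ab <- c(rac1_tot = rac1_tot, rhoa_tot = rhoa_tot, pak_tot = pak_tot,
          gefh1_tot = gefh1_tot, s1433_tot = s1433_tot,
          racgap_tot = racgap_tot)
  validate_abundances(ab)
  structure(ab, class = "rr_abundances")
}

abundance_names <- function() {
  c("rac1_tot", "rhoa_tot", "pak_tot", "gefh1_tot", "s1433_tot",
    "racgap_tot")
}

#' Names of the abundance axes sampled in abundance-space scans
#'
#' The five totals varied in multi-dimensional stability scans
#' (Rac1, RhoA, PAK, GEF-H1, 14-3-3); the Rac GAP total is held fixed.
#'
#' @return Character vector of length 5.
#' @export
sampled_axes <- function() {
  c("rac1_tot", "rhoa_tot", "pak_tot", "gefh1_tot", "s1433_tot")
}

validate_abundances <- function(ab) {
  need <- abundance_names()
  missing <- setdiff(need, names(ab))
  if (length(missing) > 0) {
    stop("missing abundance field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in need) {
    v <- ab[[nm]]
    if (!is.finite(v)) stop("abundance '", nm, "' is not finite", call. = FALSE)
    if (v < 0) stop("abundance '", nm, "' is negative (", v, " nM)",
                    call. = FALSE)
  }
  invisible(ab)
}

as_abundances <- function(x) {
  ab <- unclass(x)[abundance_names()]
  names(ab) <- abundance_names()
  validate_abundances(ab)
  structure(ab, class = "rr_abundances")
}

#' @export
print.rr_abundances <- function(x, ...) {
  cat("Total moiety abundances (nM):\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}
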