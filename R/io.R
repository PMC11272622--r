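#' Read a fabric property table
#'
#' Reads a CSV in the measured-table schema with display units in the
#' headers — `subject,class,position,R_F_cm,L_F_cm,h_mm,MD_kg_m3,E_F_MPa,
#' E_Fy_MPa,v_F,G_F_MPa` — and converts to SI columns
#' `R_F, L_F, h` (m), `MD` (kg/m^3), `E_F, E_Fy, G_F` (Pa), `v_F`.
#'
#' @param path CSV path.
#' @return data frame with one row per tube in SI units.
#' @seealso [as_fabric_spec()] to turn one row into a [fabric_spec()].
#' @export
read_fabric_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject", "class", "position", "R_F_cm", "L_F_cm", "h_mm",
           "MD_kg_m3", "E_F_MPa", "E_Fy_MPa", "v_F", "G_F_MPa")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("fabric CSV missing columns: ",
                         paste(miss, collapse = ", "))
  data.frame(subject = df$subject, class = df$class, position = df$position,
             R_F = df$R_F_cm / 100, L_F = df$L_F_cm / 100,
             h = df$h_mm / 1000, MD = df$MD_kg_m3, E_F = df$E_F_MPa * 1e6,
             E_Fy = df$E_Fy_MPa * 1e6, v_F = df$v_F, G_F = df$G_F_MPa * 1e6)
}

#' Read shear-wave elastography records
#'
#' Accepts either raw velocities (`velocity_m_s`, converted through
#' [swe_modulus()]) or moduli in MPa (`modulus_MPa`), with columns
#' `subject,position` and optional `rho_m`.
#'
#' @param path CSV path.
#' @return data frame with `subject`, `position`, `modulus_pa` (plus the raw
#'   columns read).
#' @export
read_swe_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject", "position") %in% names(df)))
    stop("SWE CSV needs 'subject' and 'position' columns")
  if (!is.null(df$modulus_MPa)) {
    df$modulus_pa <- df$modulus_MPa * 1e6
  } else if (!is.null(df$velocity_m_s)) {
    rho <- if (is.null(df$rho_m)) 1000 else df$rho_m
    df$modulus_pa <- swe_modulus(df$velocity_m_s, rho_m = rho)
  } else {
    stop("SWE CSV needs a 'velocity_m_s' or 'modulus_MPa' column")
  }
  df
}

#' Reference fabric batch used in the worked examples
#'
#' Measured properties of the knitted compression tubes worn by the three
#' reference subjects (two compression classes, four leg positions each),
#' in SI units; same schema as [read_fabric_csv()] output.
#'
#' @return data frame with 24 rows.
#' @export
reference_fabrics <- function() {
  tab <- rbind(
    c("S1","I","B",  2.52,6.0,0.66,479.3,0.35,0.16,0.21,0.14),
    c("S1","I","B1", 2.79,6.5,0.67,468.2,0.33,0.15,0.21,0.14),
    c("S1","I","C",  3.57,7.5,0.68,481.3,0.37,0.21,0.20,0.17),
    c("S1","I","D",  3.50,7.0,0.67,480.6,0.38,0.20,0.20,0.16),
    c("S1","III","B", 2.42,6.0,0.62,503.6,0.42,0.14,0.22,0.17),
    c("S1","III","B1",2.79,6.5,0.64,481.5,0.41,0.17,0.23,0.17),
    c("S1","III","C", 3.25,7.5,0.66,479.3,0.35,0.16,0.21,0.14),
    c("S1","III","D", 3.22,7.0,0.68,468.2,0.33,0.15,0.21,0.14),
    c("S2","I","B",  2.84,5.5,0.69,484.7,0.38,0.21,0.21,0.14),
    c("S2","I","B1", 3.22,6.0,0.67,468.2,0.37,0.15,0.21,0.15),
    c("S2","I","C",  3.57,6.5,0.67,486.0,0.38,0.21,0.20,0.15),
    c("S2","I","D",  3.50,6.0,0.66,485.4,0.37,0.20,0.19,0.14),
    c("S2","III","B", 2.83,5.5,0.62,503.7,0.45,0.19,0.23,0.18),
    c("S2","III","B1",2.87,6.0,0.67,484.9,0.38,0.22,0.20,0.15),
    c("S2","III","C", 3.22,6.5,0.68,468.2,0.34,0.15,0.20,0.14),
    c("S2","III","D", 3.25,6.0,0.66,480.1,0.33,0.16,0.20,0.14),
    c("S3","I","B",  2.79,5.5,0.68,468.2,0.33,0.15,0.21,0.14),
    c("S3","I","B1", 3.22,6.0,0.68,484.4,0.38,0.21,0.21,0.15),
    c("S3","I","C",  3.50,7.0,0.67,487.3,0.38,0.21,0.20,0.16),
    c("S3","I","D",  3.57,6.5,0.67,486.3,0.38,0.21,0.21,0.15),
    c("S3","III","B", 2.80,5.5,0.64,532.7,0.76,0.27,0.25,0.30),
    c("S3","III","B1",2.83,6.0,0.62,503.6,0.42,0.18,0.22,0.17),
    c("S3","III","C", 3.25,7.0,0.66,479.3,0.35,0.16,0.21,0.14),
    c("S3","III","D", 3.22,6.5,0.68,468.2,0.33,0.15,0.21,0.14))
  df <- data.frame(subject = tab[, 1], class = tab[, 2], position = tab[, 3],
                   stringsAsFactors = FALSE)
  num <- apply(tab[, 4:11], 2, as.numeric)
  df$R_F <- num[, 1] / 100; df$L_F <- num[, 2] / 100
  df$h <- num[, 3] / 1000;  df$MD <- num[, 4]
  df$E_F <- num[, 5] * 1e6; df$E_Fy <- num[, 6] * 1e6
  df$v_F <- num[, 7];       df$G_F <- num[, 8] * 1e6
  df
}

#' Reference elastography moduli of the three subjects
#'
#' Regional (ankle B / calf C) tissue Young's moduli measured by shear-wave
#' elastography for the three reference subjects, in Pa. Note the S1 row of
#' the source table prints a mean (0.002040 MPa) that is not the mean of its
#' two printed regional values (0.002060 MPa); [mean_swe_modulus()]
#' implements the plain mean.
#'
#' @return data frame with `subject`, `position`, `modulus_pa`.
#' @export
reference_swe <- function() {
  data.frame(subject = rep(c("S1", "S2", "S3"), each = 2),
             position = rep(c("B", "C"), 3),
             modulus_pa = c(1975, 2145, 2678, 3273, 3700, 1800))
}
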