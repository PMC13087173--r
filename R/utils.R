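# Internal helpers: condition classes, element-symbol handling, file access.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation problems (bad values, broken invariants) and I/O problems carry
# distinct condition classes so the CLI can map them to stable exit codes.
stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ecotox_validation_error", "ecotox_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ecotox_io_error", "ecotox_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ecotox_config_error", "ecotox_validation_error",
                                "ecotox_error")))
}

# IUPAC element symbols, periods 1-7.
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

# Case-normalize an element symbol ("SE" -> "Se"); unknown symbols error.
normalize_element <- function(x, strict = TRUE) {
  x <- trimws(as.character(x))
  out <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  if (strict) {
    bad <- unique(out[!is.na(out) & !(out %in% .element_symbols)])
    if (length(bad))
      stop_validation("unknown element symbol(s): %s", paste(bad, collapse = ", "))
  }
  out
}

.tissues <- c("muscle", "liver")
.authorities <- c("Brazil", "MERCOSUL", "Chile", "FAO", "WHO_FAO_Codex")

extdata_file <- function(name) {
  path <- system.file("extdata", name, package = "ecotoxfish")
  if (!nzchar(path)) stop_io("packaged data file not found: %s", name)
  path
}

# Stable ordering used by every report writer.
order_by <- function(df, cols) {
  cols <- intersect(cols, names(df))
  if (!nrow(df) || !length(cols)) return(df)
  df[do.call(order, df[cols]), , drop = FALSE]
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
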