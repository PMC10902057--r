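# Lipid shorthand parsing, elemental composition, monoisotopic [M-H]- m/z,
# and peak annotation against a species library.

# Monoisotopic atomic masses (Da). Electron mass needed for ion m/z.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)
.ELECTRON_MASS <- 0.000548579909

# Head-group/backbone compositions for a diacyl glycerophospholipid or the
# sphingolipid backbones, as functions of total acyl/chain carbons C and
# total double bonds D. Ether (plasmanyl) species replace one ester linkage
# by an ether: one O fewer, two H more.
.CLASS_COMPOSITION <- list(
  PC = function(C, D) c(C = C + 8, H = 2 * C + 16 - 2 * D, N = 1, O = 8, P = 1),
  PE = function(C, D) c(C = C + 5, H = 2 * C + 10 - 2 * D, N = 1, O = 8, P = 1),
  PS = function(C, D) c(C = C + 6, H = 2 * C + 10 - 2 * D, N = 1, O = 10, P = 1),
  PG = function(C, D) c(C = C + 6, H = 2 * C + 11 - 2 * D, O = 10, P = 1),
  PI = function(C, D) c(C = C + 9, H = 2 * C + 15 - 2 * D, O = 13, P = 1),
  SM = function(C, D) c(C = C + 5, H = 2 * C + 13 - 2 * D, N = 2, O = 6, P = 1),
  ST = function(C, D) c(C = C + 6, H = 2 * C + 11 - 2 * D, N = 1, O = 11, S = 1)
)

.LIPID_CLASSES <- c("PC", "PC-E", "PE", "PE-E", "PI", "PS", "PG", "SM", "ST")

#' Parse a lipid shorthand name
#'
#' Accepts the sum-composition grammar `CLASS C:D[e]` (e.g. `"PI 38:4"`,
#' `"PE 38:6e"`) and the sn-resolved form `CLASS C1:D1/C2:D2` (e.g.
#' `"PI 18:0/22:6"`). A trailing `e` marks an ether (plasmanyl) species and
#' moves the class to its ether counterpart (`PC` to `PC-E`, `PE` to
#' `PE-E`). Explicit ether class prefixes (`"PC-E 34:1"`) are also accepted.
#'
#' @param name character scalar, the shorthand name.
#' @return An object of class `lipid_species`: a list with `name`, `class`,
#'   `carbons`, `double_bonds`, `ether`, and (sn-resolved input only)
#'   `chains`, a 2x2 matrix of per-chain carbons and double bonds.
#' @examples
#' parse_shorthand("PI 38:4")
#' parse_shorthand("PE 38:6e")$class   # "PE-E"
#' parse_shorthand("PI 18:0/22:6")$carbons  # 40
#' @export
parse_shorthand <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regexec("^([A-Za-z]+(?:-E)?)[ ]?(\\d+):(\\d+)(e?)$", name)
  r <- regmatches(name, m)[[1]]
  chains <- NULL
  if (length(r) == 0L) {
    m2 <- regexec("^([A-Za-z]+(?:-E)?)[ ](\\d+):(\\d+)/(\\d+):(\\d+)(e?)$", name)
    r2 <- regmatches(name, m2)[[1]]
    if (length(r2) == 0L) {
      stop("malformed lipid shorthand at position 1: '", name,
           "' (expected CLASS C:D[e] or CLASS C1:D1/C2:D2)")
    }
    cls <- r2[2]
    c1 <- as.integer(r2[3]); d1 <- as.integer(r2[4])
    c2 <- as.integer(r2[5]); d2 <- as.integer(r2[6])
    carbons <- c1 + c2; db <- d1 + d2
    ether <- nzchar(r2[7])
    chains <- matrix(c(c1, d1, c2, d2), nrow = 2, byrow = TRUE,
                     dimnames = list(c("sn1", "sn2"), c("carbons", "double_bonds")))
  } else {
    cls <- r[2]
    carbons <- as.integer(r[3]); db <- as.integer(r[4])
    ether <- nzchar(r[5])
  }
  if (ether && cls %in% c("PC", "PE")) cls <- paste0(cls, "-E")
  if (grepl("-E$", cls)) ether <- TRUE
  if (!cls %in% .LIPID_CLASSES) {
    stop("malformed lipid shorthand: unknown class '", cls, "' in '", name, "'")
  }
  if (carbons <= db) {
    stop("malformed lipid shorthand: carbons must exceed double bonds in '",
         name, "'")
  }
  structure(list(name = format_shorthand_fields(cls, carbons, db, ether, chains),
                 class = cls, carbons = carbons, double_bonds = db,
                 ether = ether, chains = chains),
            class = "lipid_species")
}

format_shorthand_fields <- function(cls, carbons, db, ether, chains = NULL) {
  base <- sub("-E$", "", cls)
  if (!is.null(chains)) {
    return(sprintf("%s %d:%d/%d:%d%s", base,
                   chains[1, 1], chains[1, 2], chains[2, 1], chains[2, 2],
                   if (ether) "e" else ""))
  }
  sprintf("%s %d:%d%s", base, carbons, db, if (ether) "e" else "")
}

#' Format a lipid species back to shorthand
#'
#' Inverse of [parse_shorthand()]; `parse -> format -> parse` is the
#' identity on the structural fields.
#'
#' @param species a `lipid_species` object.
#' @return character scalar shorthand name.
#' @export
format_shorthand <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  species$name
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s  class=%s C=%d DB=%d%s\n", x$name, x$class,
              x$carbons, x$double_bonds, if (x$ether) " ether" else ""))
  invisible(x)
}

#' Elemental formula of a lipid species
#'
#' Builds the neutral-species elemental composition from the documented
#' class backbone compositions (diacyl glycerophospholipids; sphingomyelin
#' and sulfatide on a d18:1-type sphingoid base; ether species have one O
#' replaced by two H).
#'
#' @param species a `lipid_species` object or shorthand name.
#' @return named integer vector of element counts (C, H, N, O, P, S).
#' @export
lipid_formula <- function(species) {
  if (is.character(species)) species <- parse_shorthand(species)
  base <- sub("-E$", "", species$class)
  comp_fun <- .CLASS_COMPOSITION[[base]]
  if (is.null(comp_fun)) stop("no composition rule for class ", species$class)
  comp <- comp_fun(species$carbons, species$double_bonds)
  if (species$ether) {
    comp["O"] <- comp["O"] - 1L
    comp["H"] <- comp["H"] + 2L
  }
  full <- c(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0)
  full[names(comp)] <- comp
  storage.mode(full) <- "integer"
  full
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula named numeric vector of element counts, or a formula
#'   string such as `"H2O"` (elements C,H,N,O,P,S).
#' @return monoisotopic mass in Da.
#' @examples
#' formula_mass("H2O")
#' @export
formula_mass <- function(formula) {
  if (is.character(formula)) formula <- .parse_formula_string(formula)
  stopifnot(all(names(formula) %in% names(.ATOMIC_MASS)))
  sum(.ATOMIC_MASS[names(formula)] * formula)
}

.parse_formula_string <- function(s) {
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", s)[[1]]
  parts <- regmatches(s, gregexpr("([A-Z][a-z]?)(\\d*)", s))[[1]]
  parts <- parts[nzchar(parts)]
  el <- sub("\\d+$", "", parts)
  n <- as.integer(sub("^[A-Za-z]+", "", parts))
  n[is.na(n)] <- 1L
  tapply(n, el, sum)
}

#' Theoretical m/z of a lipid species for a given adduct
#'
#' Only the deprotonated ion `[M-H]-` is supported by default: negative-ion
#' MALDI of these lipid classes is dominated by it, which keeps annotation
#' unambiguous compared to polarity regimes with many adducts.
#'
#' @param species `lipid_species` object or shorthand name.
#' @param adduct adduct label; only `"[M-H]-"` is implemented.
#' @return m/z value (Da) of the ion.
#' @examples
#' species_mz("PI 38:4")   # 885.5499
#' @export
species_mz <- function(species, adduct = "[M-H]-") {
  if (!identical(adduct, "[M-H]-")) {
    stop("unsupported adduct: ", adduct, " (only \"[M-H]-\" is implemented)")
  }
  m <- formula_mass(lipid_formula(species))
  m - .ATOMIC_MASS[["H"]] + .ELECTRON_MASS
}

#' Format an elemental composition as a Hill-order formula string
#' @param formula named integer vector of element counts.
#' @return character scalar, e.g. `"C47H83O13P"`.
#' @export
format_formula <- function(formula) {
  formula <- formula[formula > 0]
  ord <- c("C", "H", setdiff(sort(names(formula)), c("C", "H")))
  ord <- ord[ord %in% names(formula)]
  paste0(vapply(ord, function(el) {
    if (formula[[el]] == 1L) el else paste0(el, formula[[el]])
  }, ""), collapse = "")
}

# Species table used to build the bundled library: one row per species with
# the trend direction each region template applies (see templates.R).
.DEFAULT_SPECIES <- c(
  # PC (diacyl) -- total PC rises toward the lesion core
  "PC 32:0", "PC 34:1", "PC 36:1", "PC 36:4", "PC 38:4", "PC 40:6",
  # PC ether -- general decrease
  "PC 32:0e", "PC 34:1e", "PC 36:4e", "PC 38:5e",
  # PE (diacyl) -- increase
  "PE 34:1", "PE 36:1", "PE 36:2", "PE 38:4", "PE 40:6",
  # PE ether -- mixed: 36:2e/40:6e down, 38:6e/38:7e/40:7e up, 36:5e peri-max
  "PE 36:2e", "PE 36:5e", "PE 38:6e", "PE 38:7e", "PE 40:6e", "PE 40:7e",
  # PI -- up in lesion (esp. 38:4, arachidonate store); abundant in grey matter
  "PI 34:1", "PI 36:1", "PI 36:4", "PI 37:4", "PI 38:4", "PI 38:5",
  "PI 38:6", "PI 40:6",
  # PS -- general decrease toward the core
  "PS 36:1", "PS 36:2", "PS 38:4", "PS 40:6",
  # PG -- fatty-acid remodelling (mixed directions)
  "PG 34:1", "PG 36:2", "PG 38:4", "PG 40:6",
  # SM -- increase (membranes of proliferating microglia)
  "SM 34:1", "SM 36:1", "SM 38:1", "SM 42:2",
  # Sulfatides -- decrease (myelin loss)
  "ST 40:1", "ST 42:1", "ST 42:2", "ST 44:2"
)

#' The bundled lipid species library
#'
#' Returns the library of negative-mode lipid species the pipeline
#' annotates against: shorthand name, class, elemental formula, neutral
#' monoisotopic mass and `[M-H]-` m/z, recomputed from the class backbone
#' compositions. A CSV copy ships in `inst/extdata/lipid_library.csv`.
#'
#' @param species character vector of shorthand names; defaults to the
#'   bundled set (~45 species over classes PC, PC-E, PE, PE-E, PI, PS, PG,
#'   SM, ST).
#' @return data.frame with columns `name`, `class`, `carbons`,
#'   `double_bonds`, `ether`, `formula`, `neutral_mass`, `mz_MH`.
#' @export
lipid_library <- function(species = .DEFAULT_SPECIES) {
  rows <- lapply(species, function(nm) {
    sp <- parse_shorthand(nm)
    f <- lipid_formula(sp)
    data.frame(name = sp$name, class = sp$class, carbons = sp$carbons,
               double_bonds = sp$double_bonds, ether = sp$ether,
               formula = format_formula(f),
               neutral_mass = formula_mass(f),
               mz_MH = species_mz(sp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mz_MH), , drop = FALSE]
}

#' Write the bundled library as CSV
#' @param path output CSV path.
#' @param library library data.frame; defaults to [lipid_library()].
#' @return `path`, invisibly.
#' @export
write_lipid_library <- function(path, library = lipid_library()) {
  utils::write.csv(library, path, row.names = FALSE)
  invisible(path)
}

#' Read a lipid library CSV
#' @param path CSV with at least columns `name`, `class`, `mz_MH`.
#' @return data.frame.
#' @export
read_lipid_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "class", "mz_MH")
  if (!all(need %in% names(lib))) {
    stop("lipid library must contain columns: ", paste(need, collapse = ", "))
  }
  lib
}

#' Annotate picked peaks against a lipid library
#'
#' Matches every peak against all library `[M-H]-` m/z values within a ppm
#' tolerance. Peaks matching several species report all candidates sorted
#' by absolute ppm error. Matches of PS species are flagged: fragmentation
#' of PI species overlaps the PS m/z region, so PS annotations from m/z
#' alone are tentative; a PS peak that also co-matches a PI species within
#' tolerance is additionally flagged as a direct PS/PI overlap.
#'
#' @param peaklist numeric vector of peak m/z values, or a `peaklist`
#'   object from [pick_peaks()].
#' @param library data.frame from [lipid_library()] or
#'   [read_lipid_library()].
#' @param tol_ppm matching tolerance in parts per million (default 5,
#'   consistent with ~60,000 mass resolution).
#' @return data.frame with one row per (peak, match) plus unannotated
#'   peaks: columns `peak_mz`, `name`, `class`, `library_mz`, `error_ppm`,
#'   `flags` (comma-separated), `n_matches`, `confidence` (always
#'   `"mz-only"` for matches).
#' @export
annotate_peaks <- function(peaklist, library = lipid_library(), tol_ppm = 5) {
  stopifnot(tol_ppm > 0, nrow(library) > 0)
  mz <- if (inherits(peaklist, "peaklist")) peaklist$mz else as.numeric(peaklist)
  out <- vector("list", length(mz))
  for (k in seq_along(mz)) {
    err_ppm <- (mz[k] - library$mz_MH) / library$mz_MH * 1e6
    hit <- which(abs(err_ppm) <= tol_ppm)
    if (length(hit) == 0L) {
      out[[k]] <- data.frame(peak_mz = mz[k], name = NA_character_,
                             class = NA_character_, library_mz = NA_real_,
                             error_ppm = NA_real_, flags = "",
                             n_matches = 0L, confidence = NA_character_,
                             stringsAsFactors = FALSE)
      next
    }
    hit <- hit[order(abs(err_ppm[hit]))]
    classes <- library$class[hit]
    flags <- character(length(hit))
    if (length(hit) > 1L) flags[] <- "ambiguous"
    ps_pi_overlap <- any(classes == "PS") && any(classes == "PI")
    for (j in seq_along(hit)) {
      f <- flags[j]
      if (classes[j] == "PS") {
        f <- paste(c(f[nzchar(f)], "PS-caution"), collapse = ",")
        if (ps_pi_overlap) f <- paste(f, "PS/PI-overlap", sep = ",")
      } else if (classes[j] == "PI" && ps_pi_overlap) {
        f <- paste(c(f[nzchar(f)], "PS/PI-overlap"), collapse = ",")
      }
      flags[j] <- f
    }
    out[[k]] <- data.frame(peak_mz = mz[k], name = library$name[hit],
                           class = classes, library_mz = library$mz_MH[hit],
                           error_ppm = err_ppm[hit], flags = flags,
                           n_matches = length(hit), confidence = "mz-only",
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
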