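# Writers for MDL Molfile V2000/V3000, SDF, TSV/DWAR tables, and the
# coordination-bond stripping used before linear-notation generation.
# Zero-order coordination bonds serialize as "any bonds" (type 8) in V2000
# and as "coordination bonds" (type 9) in V3000. All writers are pure:
# identical inputs yield byte-identical output.

.molfile_bond_type <- function(order, v3000 = FALSE) {
  ifelse(order == 0L, if (v3000) 9L else 8L, order)
}

#' Write an MDL Molfile V2000 block
#'
#' Formal charges are carried in `M  CHG` property lines (full fidelity
#' beyond +-3), radicals in `M  RAD` lines; zero-order coordination bonds
#' become bond type 8. The format cannot describe molecules with more than
#' 999 atoms or 999 bonds.
#'
#' @param st A perceived [chemical_structure()].
#' @param title Header title line (entry identifier).
#' @return Character scalar with the molfile text (no trailing newline).
#' @export
write_molfile_v2000 <- function(st, title = "") {
  n <- nrow(st$atoms)
  m <- nrow(st$bonds)
  if (n > 999 || m > 999) {
    stop("MDL Molfile V2000 cannot describe more than 999 atoms or 999 bonds (",
         n, " atoms, ", m, " bonds)")
  }
  lines <- c(title, "  cifchem          3D", "")
  lines <- c(lines, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  lines <- c(lines, sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    st$atoms$x, st$atoms$y, st$atoms$z, st$atoms$element))
  if (m > 0) {
    lines <- c(lines, sprintf("%3d%3d%3d  0",
                              st$bonds$i, st$bonds$j,
                              .molfile_bond_type(st$bonds$order)))
  }
  chg <- which(st$atoms$charge != 0L)
  while (length(chg) > 0) {
    take <- chg[seq_len(min(8, length(chg)))]
    chg <- chg[-seq_len(min(8, length(chg)))]
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(take)),
                             paste(sprintf("%4d%4d", take,
                                           st$atoms$charge[take]),
                                   collapse = "")))
  }
  rad <- which(st$atoms$radical)
  while (length(rad) > 0) {
    take <- rad[seq_len(min(8, length(rad)))]
    rad <- rad[-seq_len(min(8, length(rad)))]
    lines <- c(lines, paste0("M  RAD", sprintf("%3d", length(take)),
                             paste(sprintf("%4d%4d", take, 2L),
                                   collapse = "")))
  }
  lines <- c(lines, "M  END")
  paste(lines, collapse = "\n")
}

#' Write an MDL Molfile V3000 block
#'
#' Zero-order coordination bonds become bond type 9; the format has no
#' 999-atom/bond limit.
#'
#' @inheritParams write_molfile_v2000
#' @return Character scalar with the molfile text.
#' @export
write_molfile_v3000 <- function(st, title = "") {
  n <- nrow(st$atoms)
  m <- nrow(st$bonds)
  lines <- c(title, "  cifchem          3D", "",
             "  0  0  0  0  0  0  0  0  0  0999 V3000",
             "M  V30 BEGIN CTAB",
             sprintf("M  V30 COUNTS %d %d 0 0 0", n, m),
             "M  V30 BEGIN ATOM")
  for (a in seq_len(n)) {
    extra <- ""
    if (st$atoms$charge[a] != 0L) {
      extra <- paste0(extra, sprintf(" CHG=%d", st$atoms$charge[a]))
    }
    if (st$atoms$radical[a]) extra <- paste0(extra, " RAD=2")
    lines <- c(lines, sprintf("M  V30 %d %s %.4f %.4f %.4f 0%s",
                              a, st$atoms$element[a],
                              st$atoms$x[a], st$atoms$y[a], st$atoms$z[a],
                              extra))
  }
  lines <- c(lines, "M  V30 END ATOM")
  if (m > 0) {
    lines <- c(lines, "M  V30 BEGIN BOND",
               sprintf("M  V30 %d %d %d %d", seq_len(m),
                       .molfile_bond_type(st$bonds$order, v3000 = TRUE),
                       st$bonds$i, st$bonds$j),
               "M  V30 END BOND")
  }
  lines <- c(lines, "M  V30 END CTAB", "M  END")
  paste(lines, collapse = "\n")
}

#' Assemble one SDF record
#'
#' @param st A perceived [chemical_structure()].
#' @param verdict An `entry_verdict` from [judge_entry()], or `NULL`.
#' @param meta Named list of extra data items (cell parameters, provenance,
#'   ...); `NULL` entries emit empty strings rather than omitting the tag.
#' @param v3000 Write the molfile block in V3000?
#' @return List of class `sdf_record` with `molfile` and `data` fields.
#' @export
sdf_record <- function(st, verdict = NULL, meta = list(), v3000 = FALSE) {
  name <- if (!is.null(st$meta$name)) st$meta$name else ""
  molfile <- if (v3000) write_molfile_v3000(st, name) else
    write_molfile_v2000(st, name)
  issues <- st$issues
  issue_str <- if (nrow(issues) == 0) "" else
    paste(sprintf("%s: %s", issues$category, issues$message), collapse = "; ")
  validity <- if (is.null(verdict)) "" else
    if (verdict$overall_valid) "valid" else
      paste0("invalid: ",
             paste(names(verdict$criteria)[!verdict$criteria], collapse = ","))
  cellstr <- if (!is.null(st$meta$cell)) {
    cc <- st$meta$cell
    sprintf("%.4f %.4f %.4f %.3f %.3f %.3f",
            cc$a, cc$b, cc$c, cc$alpha, cc$beta, cc$gamma)
  } else ""
  prov <- st$meta$provenance
  blank <- function(x) if (is.null(x) || is.na(x)) "" else as.character(x)
  data <- c(list(
    COD_ID = name,
    COD_SDF_ISSUES = issue_str,
    COD_SDF_VALIDITY_STATUS = validity,
    DOI = blank(prov$doi),
    CITATION = blank(prov$journal),
    SPACE_GROUP_NUMBER = blank(st$meta$space_group_number),
    CELL_PARAMETERS = cellstr), meta)
  structure(list(molfile = molfile, data = data), class = "sdf_record")
}

#' Write SDF text from a list of records
#'
#' Every record, valid or not, is emitted; failing entries carry their status
#' in `COD_SDF_VALIDITY_STATUS` instead of being omitted.
#'
#' @param records List of [sdf_record()]s.
#' @return Character scalar with the SDF text.
#' @export
write_sdf <- function(records) {
  blocks <- vapply(records, function(rec) {
    items <- vapply(names(rec$data), function(tag) {
      sprintf("> <%s>\n%s\n", tag, as.character(rec$data[[tag]]))
    }, character(1))
    paste0(rec$molfile, "\n", paste(items, collapse = "\n"), "\n$$$$")
  }, character(1))
  paste0(paste(blocks, collapse = "\n"), "\n")
}

#' Strip zero-order coordination bonds
#'
#' @param st A [chemical_structure()].
#' @param mode `"remove"` deletes all order-0 bonds (separating ligands from
#'   the metal centre), `"to_single"` reassigns them order 1. All other bonds
#'   are untouched.
#' @return Updated structure.
#' @export
strip_coordination_bonds <- function(st, mode = c("remove", "to_single")) {
  mode <- match.arg(mode)
  zero <- st$bonds$order == 0L
  if (mode == "remove") {
    st$bonds <- st$bonds[!zero, , drop = FALSE]
    rownames(st$bonds) <- NULL
  } else {
    st$bonds$order[zero] <- 1L
  }
  st
}

.tsv_escape <- function(x) gsub("[\t\n]", " ", x)

#' Write entries as a TSV / DWAR-style table
#'
#' Columns: entry identifier, the crystal-scope SMILES encoding of the
#' structure, the "C1-Problems" issue list and the "Is valid entry" verdict.
#'
#' @param entries List; each element has `id`, `structure` (a perceived
#'   [chemical_structure()]) and `verdict` (an `entry_verdict`).
#' @param mode `"plain"` emits bare rows, `"header"` prepends the column-name
#'   row, `"dwar"` additionally prepends a minimal DataWarrior-style file
#'   header block. The data body is identical across modes.
#' @return Character scalar of TSV text.
#' @export
write_tsv <- function(entries, mode = c("plain", "header", "dwar")) {
  mode <- match.arg(mode)
  cols <- c("Identifier", "Smiles", "C1-Problems", "Is valid entry")
  rows <- vapply(entries, function(e) {
    smi <- paste(to_smiles(e$structure, scope = "crystal"), collapse = ".")
    probs <- if (nrow(e$structure$issues) == 0) "" else
      paste(sprintf("%s: %s", e$structure$issues$category,
                    e$structure$issues$message), collapse = "; ")
    valid <- if (isTRUE(e$verdict$overall_valid)) "true" else "false"
    paste(.tsv_escape(c(e$id, smi, probs, valid)), collapse = "\t")
  }, character(1))
  head <- character(0)
  if (mode == "dwar") {
    head <- c("<datawarrior-fileinfo>",
              "<version=\"3.1\">",
              sprintf("<rowcount=\"%d\">", length(entries)),
              "</datawarrior-fileinfo>",
              "<column properties>",
              "<columnName=\"Smiles\">",
              "<columnProperty=\"specialType\tsmiles\">",
              "</column properties>")
  }
  if (mode %in% c("header", "dwar")) {
    head <- c(head, paste(cols, collapse = "\t"))
  }
  paste0(paste(c(head, rows), collapse = "\n"), "\n")
}
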