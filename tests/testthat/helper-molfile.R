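# Independent minimal MDL Molfile readers used as round-trip oracles. These
# parse the fixed-width V2000 and keyword V3000 grammars directly and share
# no code with the package writers.

parse_v2000 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  atoms <- lapply(seq_len(natoms), function(k) {
    ln <- lines[4 + k]
    list(x = as.numeric(substr(ln, 1, 10)),
         y = as.numeric(substr(ln, 11, 20)),
         z = as.numeric(substr(ln, 21, 30)),
         element = trimws(substr(ln, 32, 34)))
  })
  bonds <- do.call(rbind, lapply(seq_len(nbonds), function(k) {
    ln <- lines[4 + natoms + k]
    data.frame(i = as.integer(substr(ln, 1, 3)),
               j = as.integer(substr(ln, 4, 6)),
               type = as.integer(substr(ln, 7, 9)))
  }))
  charges <- integer(natoms)
  radicals <- integer(0)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    nn <- as.integer(substr(ln, 7, 9))
    rest <- substring(ln, 10)
    vals <- as.integer(strsplit(trimws(rest), "\\s+")[[1]])
    for (k in seq_len(nn)) {
      charges[vals[2 * k - 1]] <- vals[2 * k]
    }
  }
  for (ln in grep("^M  RAD", lines, value = TRUE)) {
    nn <- as.integer(substr(ln, 7, 9))
    vals <- as.integer(strsplit(trimws(substring(ln, 10)), "\\s+")[[1]])
    radicals <- c(radicals, vals[seq(1, 2 * nn, by = 2)])
  }
  list(natoms = natoms, nbonds = nbonds,
       elements = vapply(atoms, `[[`, character(1), "element"),
       xyz = t(vapply(atoms, function(a) c(a$x, a$y, a$z), numeric(3))),
       bonds = if (is.null(bonds)) data.frame() else bonds,
       charges = charges, radicals = radicals)
}

parse_v3000 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- grep("^M  V30 COUNTS", lines, value = TRUE)
  cvals <- strsplit(trimws(sub("^M  V30 COUNTS", "", counts)), "\\s+")[[1]]
  natoms <- as.integer(cvals[1]); nbonds <- as.integer(cvals[2])
  a0 <- grep("^M  V30 BEGIN ATOM", lines)
  atom_lines <- lines[seq(a0 + 1, length.out = natoms)]
  elements <- character(natoms); charges <- integer(natoms)
  for (ln in atom_lines) {
    f <- strsplit(trimws(sub("^M  V30 ", "", ln)), "\\s+")[[1]]
    idx <- as.integer(f[1])
    elements[idx] <- f[2]
    chg <- grep("^CHG=", f, value = TRUE)
    if (length(chg) > 0) charges[idx] <- as.integer(sub("CHG=", "", chg))
  }
  bonds <- data.frame(i = integer(0), j = integer(0), type = integer(0))
  b0 <- grep("^M  V30 BEGIN BOND", lines)
  if (length(b0) == 1 && nbonds > 0) {
    for (ln in lines[seq(b0 + 1, length.out = nbonds)]) {
      f <- as.integer(strsplit(trimws(sub("^M  V30 ", "", ln)), "\\s+")[[1]])
      bonds <- rbind(bonds, data.frame(i = f[3], j = f[4], type = f[2]))
    }
  }
  list(natoms = natoms, nbonds = nbonds, elements = elements,
       charges = charges, bonds = bonds)
}
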