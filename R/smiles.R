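#' Parse a SMILES string into a molecular graph
#'
#' Builds the heavy-atom graph encoded by a SMILES string: ring closures,
#' branches, explicit bond orders, bracket atoms with charges and hydrogen
#' counts, and dot-separated components. Aromatic rings are kekulized on
#' parse, so every bond in the returned graph has a discrete order of 1, 2
#' or 3 — the representation builders draw one stick per order unit and
#' never need a delocalized bond type. Implicit hydrogens are *not* added
#' here; see [add_hydrogens()].
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `molecule_graph`: a list with
#'   `atoms` (data frame: `element`, `aromatic`, `charge`, `hcount` —
#'   `NA` means "implicit, fill at hydrogenation" — and `chiral`),
#'   `bonds` (data frame: `a`, `b`, `order`), and `source_smiles`.
#' @examples
#' g <- parse_smiles("C1CCCCC1")
#' nrow(g$atoms) # 6
#' nrow(g$bonds) # 6
#' @seealso [add_hydrogens()], [embed_conformer()]
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    abort_mf("molforge_invalid_smiles", "SMILES input must be a single string")
  }
  s <- trimws(smiles)
  if (!nzchar(s)) abort_mf("molforge_empty_input", "empty SMILES string")

  bad <- function(why) {
    abort_mf("molforge_invalid_smiles",
             sprintf("invalid SMILES %s: %s", dQuote(s, q = FALSE), why))
  }

  element <- character(0); aromatic <- logical(0)
  charge <- integer(0); hcount <- integer(0); chiral <- character(0)
  b_a <- integer(0); b_b <- integer(0); b_sym <- character(0)

  add_atom <- function(el, arom, chg, hc, chi) {
    element[[length(element) + 1L]] <<- el
    aromatic[[length(aromatic) + 1L]] <<- arom
    charge[[length(charge) + 1L]] <<- chg
    hcount[[length(hcount) + 1L]] <<- hc
    chiral[[length(chiral) + 1L]] <<- chi
    length(element)
  }
  add_bond <- function(a, b, sym) {
    if (a == b) bad("bond from an atom to itself")
    if (any((b_a == a & b_b == b) | (b_a == b & b_b == a))) {
      bad("duplicate bond")
    }
    b_a[[length(b_a) + 1L]] <<- a
    b_b[[length(b_b) + 1L]] <<- b
    b_sym[[length(b_sym) + 1L]] <<- sym
  }

  organic1 <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromatic1 <- c("b", "c", "n", "o", "p", "s")

  n <- nchar(s)
  i <- 1L
  prev <- NA_integer_         # current attachment atom
  pending <- ""                # bond symbol awaiting its second atom
  branch_stack <- integer(0)
  rings <- list()              # ring-bond number -> list(atom, sym)

  close_ring <- function(key) {
    if (is.na(prev)) bad("ring-closure digit before any atom")
    if (!is.null(rings[[key]])) {
      open <- rings[[key]]
      sym <- if (nzchar(pending) && nzchar(open$sym)) {
        if (pending != open$sym) bad(sprintf("conflicting ring-bond orders for ring %s", key))
        pending
      } else if (nzchar(pending)) pending else open$sym
      add_bond(open$atom, prev, sym)
      rings[[key]] <<- NULL
    } else {
      rings[[key]] <- list(atom = prev, sym = pending)
      rings <<- rings
    }
    pending <<- ""
  }

  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (nzchar(pending)) bad("two consecutive bond symbols")
      pending <- ch
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) bad("branch opened before any atom")
      if (nzchar(pending)) bad("bond symbol before a branch opening")
      branch_stack <- c(branch_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(branch_stack) == 0L) bad("unmatched closing parenthesis")
      if (nzchar(pending)) bad("dangling bond symbol at branch close")
      prev <- branch_stack[[length(branch_stack)]]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (ch == ".") {
      if (nzchar(pending)) bad("bond symbol across a dot separator")
      prev <- NA_integer_
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(s, i + 1L, i + 2L))) {
        bad("'%' ring closure needs two digits")
      }
      close_ring(substr(s, i + 1L, i + 2L))
      i <- i + 3L
    } else if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0L) bad("unclosed bracket atom")
      body <- substr(s, i + 1L, i + j - 2L)
      m <- regexec("^([0-9]*)([A-Z][a-z]?|[a-z][a-z]?)(@@|@)?(H([0-9]*))?(\\+[0-9]+|-[0-9]+|\\++|-+)?$", body)
      parts <- regmatches(body, m)[[1]]
      if (length(parts) == 0L) bad(sprintf("malformed bracket atom [%s]", body))
      el_raw <- parts[[3]]
      arom <- el_raw == tolower(el_raw)
      el <- paste0(toupper(substr(el_raw, 1, 1)), substr(el_raw, 2, nchar(el_raw)))
      hc <- if (nzchar(parts[[5]])) {
        if (nzchar(parts[[6]])) as.integer(parts[[6]]) else 1L
      } else 0L
      chg_str <- parts[[7]]
      chg <- if (!nzchar(chg_str)) 0L
      else if (grepl("^[+-][0-9]+$", chg_str)) as.integer(chg_str)
      else (if (substr(chg_str, 1, 1) == "+") 1L else -1L) * nchar(chg_str)
      a <- add_atom(el, arom, chg, hc, parts[[4]])
      if (!is.na(prev)) add_bond(prev, a, pending)
      else if (nzchar(pending)) bad("bond symbol with no preceding atom")
      pending <- ""
      prev <- a
      i <- i + j
    } else {
      two <- substr(s, i, min(i + 1L, n))
      if (two %in% c("Cl", "Br")) {
        a <- add_atom(two, FALSE, 0L, NA_integer_, "")
        i <- i + 2L
      } else if (ch %in% organic1) {
        a <- add_atom(ch, FALSE, 0L, NA_integer_, "")
        i <- i + 1L
      } else if (ch %in% aromatic1) {
        a <- add_atom(toupper(ch), TRUE, 0L, NA_integer_, "")
        i <- i + 1L
      } else {
        bad(sprintf("unexpected character %s at position %d", dQuote(ch, q = FALSE), i))
      }
      if (!is.na(prev)) add_bond(prev, a, pending)
      else if (nzchar(pending)) bad("bond symbol with no preceding atom")
      pending <- ""
      prev <- a
    }
  }

  if (nzchar(pending)) bad("trailing bond symbol")
  if (length(branch_stack) > 0L) bad("unclosed branch")
  if (length(rings) > 0L) {
    bad(sprintf("unclosed ring bond(s): %s", paste(names(rings), collapse = ", ")))
  }
  if (length(element) == 0L) bad("no atoms")

  atoms <- data.frame(element = element, aromatic = aromatic, charge = charge,
                      hcount = hcount, chiral = chiral, stringsAsFactors = FALSE)
  bonds <- data.frame(a = b_a, b = b_b, sym = b_sym, stringsAsFactors = FALSE)
  g <- structure(
    list(atoms = atoms, bonds = bonds, source_smiles = smiles),
    class = "molecule_graph"
  )
  kekulize(g, bad)
}

# Resolve bond symbols to discrete orders, finding a perfect matching of
# double bonds over the aromatic system (backtracking; molecules at teaching
# scale keep this cheap).
kekulize <- function(g, bad) {
  atoms <- g$atoms
  bonds <- g$bonds
  n_at <- nrow(atoms)
  # A bond is aromatic when both ends are aromatic atoms and no explicit
  # single/double/triple symbol overrides it (biphenyl's "-" stays single).
  arom_bond <- atoms$aromatic[bonds$a] & atoms$aromatic[bonds$b] &
    bonds$sym %in% c("", ":")
  if (any(bonds$sym == ":" & !arom_bond)) bad("':' bond between non-aromatic atoms")
  order <- ifelse(bonds$sym == "=", 2L, ifelse(bonds$sym == "#", 3L, 1L))

  if (any(arom_bond)) {
    # An aromatic atom needs one double bond when its sigma framework
    # (all bonds counted once, plus any explicit bracket hydrogens) leaves
    # spare valence; exocyclic doubles and pyrrole-type [nH] leave none.
    sigma <- numeric(n_at)
    for (k in seq_len(nrow(bonds))) {
      o <- if (arom_bond[k]) 1L else order[k]
      sigma[bonds$a[k]] <- sigma[bonds$a[k]] + o
      sigma[bonds$b[k]] <- sigma[bonds$b[k]] + o
    }
    sigma <- sigma + ifelse(is.na(atoms$hcount), 0L, atoms$hcount)
    vef <- vapply(seq_len(n_at), function(i) {
      v <- effective_valence(atoms$element[i], atoms$charge[i])
      if (is.na(v)) 0 else v
    }, numeric(1))
    needs <- atoms$aromatic & (vef - sigma >= 1)

    adj <- lapply(seq_len(n_at), function(i) integer(0))
    for (k in which(arom_bond)) {
      a <- bonds$a[k]; b <- bonds$b[k]
      if (needs[a] && needs[b]) {
        adj[[a]] <- c(adj[[a]], k)
        adj[[b]] <- c(adj[[b]], k)
      }
    }
    matched <- rep(FALSE, n_at)
    dbl <- logical(nrow(bonds))
    need_idx <- which(needs)
    solve <- function(pos) {
      while (pos <= length(need_idx) && matched[need_idx[pos]]) pos <- pos + 1L
      if (pos > length(need_idx)) return(TRUE)
      i <- need_idx[pos]
      for (k in adj[[i]]) {
        j <- if (bonds$a[k] == i) bonds$b[k] else bonds$a[k]
        if (!matched[j]) {
          matched[i] <<- TRUE; matched[j] <<- TRUE; dbl[k] <<- TRUE
          if (solve(pos + 1L)) return(TRUE)
          matched[i] <<- FALSE; matched[j] <<- FALSE; dbl[k] <<- FALSE
        }
      }
      FALSE
    }
    if (!solve(1L)) bad("aromatic system cannot be kekulized")
    order[arom_bond] <- ifelse(dbl[arom_bond], 2L, 1L)
  }

  g$bonds <- data.frame(a = bonds$a, b = bonds$b, order = order)
  g
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph> %s: %d atoms, %d bonds\n",
              x$source_smiles, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

bond_order_sums <- function(g) {
  s <- numeric(nrow(g$atoms))
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      s[g$bonds$a[k]] <- s[g$bonds$a[k]] + g$bonds$order[k]
      s[g$bonds$b[k]] <- s[g$bonds$b[k]] + g$bonds$order[k]
    }
  }
  s
}

#' Add explicit hydrogen atoms to a molecular graph
#'
#' Appends one H atom per unit of unused valence, so that every atom of a
#' tabulated element reaches its standard valence (adjusted for formal
#' charge). Bracket atoms use their explicit hydrogen count. Heavy atoms keep
#' their original indices; hydrogens are appended after them, which the mesh
#' and layout stages rely on.
#'
#' @param graph A `molecule_graph` from [parse_smiles()].
#' @return A `molecule_graph` with explicit hydrogens. Applying the function
#'   twice is a no-op.
#' @examples
#' g <- add_hydrogens(parse_smiles("C"))
#' nrow(g$atoms) # 5: CH4
#' @export
add_hydrogens <- function(graph) {
  stopifnot(inherits(graph, "molecule_graph"))
  atoms <- graph$atoms
  sums <- bond_order_sums(graph)
  n_heavy <- nrow(atoms)
  h_for <- integer(n_heavy)
  for (i in seq_len(n_heavy)) {
    if (!is.na(atoms$hcount[i])) {
      h_for[i] <- atoms$hcount[i]
      next
    }
    v <- effective_valence(atoms$element[i], atoms$charge[i])
    if (is.na(v)) { h_for[i] <- 0L; next }
    free <- v - sums[i]
    if (free < 0) {
      abort_mf("molforge_valence_error", sprintf(
        "atom %d (%s) in %s exceeds its standard valence (%g bonds for valence %g)",
        i, atoms$element[i], dQuote(graph$source_smiles, q = FALSE), sums[i], v))
    }
    h_for[i] <- as.integer(free)
  }
  total_h <- sum(h_for)
  if (total_h == 0L) {
    graph$atoms$hcount <- 0L
    return(graph)
  }
  h_atoms <- data.frame(
    element = rep("H", total_h), aromatic = FALSE, charge = 0L,
    hcount = 0L, chiral = "", stringsAsFactors = FALSE
  )
  atoms$hcount <- 0L
  new_bonds <- data.frame(
    a = rep(seq_len(n_heavy), h_for),
    b = n_heavy + seq_len(total_h),
    order = 1L
  )
  graph$atoms <- rbind(atoms, h_atoms)
  graph$bonds <- rbind(graph$bonds, new_bonds)
  graph
}

#' Resolve user input to a SMILES string
#'
#' Looks the (lowercased, trimmed) input up in the bundled offline dictionary
#' of common trivial names; anything not in the dictionary is returned
#' unchanged and left for [parse_smiles()] to validate. No network lookup is
#' ever performed.
#'
#' @param text A trivial name (e.g. `"ethanol"`) or a SMILES string.
#' @return A SMILES string.
#' @examples
#' resolve_input("ethanol") # "CCO"
#' resolve_input("CCO")     # unchanged
#' @export
resolve_input <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    abort_mf("molforge_empty_input", "empty input")
  }
  key <- tolower(trimws(text))
  dict <- trivial_names()
  i <- match(key, dict$name)
  if (!is.na(i)) dict$smiles[i] else trimws(text)
}

#' Bundled trivial-name dictionary
#'
#' @return Data frame with columns `name` (lowercase) and `smiles`.
#' @export
trivial_names <- function() {
  path <- system.file("extdata", "trivial_names.csv", package = "molforge")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Split a comma-separated batch of inputs
#'
#' Batch requests are comma-separated lists of SMILES strings or trivial
#' names, e.g. `"CCO, CO"`. Order is preserved; tokens are trimmed.
#'
#' @param text The raw batch string.
#' @return A `batch_input` object (character vector of entries with a
#'   `source` attribute).
#' @examples
#' split_batch_text("CCO, CO")
#' @export
split_batch_text <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    abort_mf("molforge_empty_input", "empty batch input")
  }
  toks <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  if (length(toks) == 0L || any(!nzchar(toks))) {
    abort_mf("molforge_empty_token", "blank entry in comma-separated batch")
  }
  new_batch_input(toks, "inline")
}

#' Read a batch of inputs from a CSV file
#'
#' Takes the first column of every non-empty row, in file order. The CSV
#' dialect is comma-separated UTF-8 with no header by default.
#'
#' @param path Path to the CSV file.
#' @param header If `TRUE`, skip the first row.
#' @return A `batch_input` object.
#' @export
read_batch_csv <- function(path, header = FALSE) {
  if (!file.exists(path)) {
    abort_mf("molforge_file_not_found", sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort_mf("molforge_empty_file", sprintf("no entries in CSV file: %s", path))
  }
  toks <- trimws(vapply(strsplit(lines, ",", fixed = TRUE),
                        function(x) x[[1]], character(1)))
  if (any(!nzchar(toks))) {
    abort_mf("molforge_empty_token", sprintf("blank first column in CSV file: %s", path))
  }
  new_batch_input(toks, "csv")
}

new_batch_input <- function(entries, source) {
  structure(entries, source = source, class = "batch_input")
}
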