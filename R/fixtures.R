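#' Linear alkane SMILES
#'
#' @param n Chain length (number of carbons), `n >= 1`.
#' @return The SMILES string `"C"` repeated `n` times; hydrogenation yields
#'   the CnH2n+2 alkane with `3n + 2` atoms and `3n + 1` bonds.
#' @examples
#' alkane_smiles(3) # "CCC"
#' @export
alkane_smiles <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    abort_mf("molforge_bad_param", "alkane length must be a positive integer")
  }
  strrep("C", as.integer(n))
}

#' Generate a synthetic batch of valid SMILES
#'
#' Deterministic fixture batches for exercising the pipeline at the batch
#' sizes the generator is meant to handle (up to several hundred models)
#' without any external data. Families are chemically trivial on purpose —
#' unbranched or lightly branched alkanes, alcohols, ethers and small
#' rings — so capacity runs measure pipeline robustness rather than
#' embedder corner cases.
#'
#' @param count Number of entries, `>= 1`.
#' @param family One of `"alkanes"` (the linear series C1, C2, ...),
#'   `"alcohols"` (primary alcohols), or `"mixed"` (seeded sample of
#'   alkanes, alcohols, ethers and rings).
#' @param seed Integer seed; equal `(count, family, seed)` always produce
#'   the same batch.
#' @return A `batch_input` character vector of `count` SMILES strings, all
#'   of which pass [parse_smiles()].
#' @examples
#' batch_fixture(2, "alkanes") # "C", "CC"
#' @export
batch_fixture <- function(count, family = c("mixed", "alkanes", "alcohols"),
                          seed = 0L) {
  if (!is.numeric(count) || length(count) != 1L || is.na(count) || count < 1) {
    abort_mf("molforge_bad_param", "fixture count must be >= 1")
  }
  count <- as.integer(count)
  family <- match.arg(family)
  entries <- switch(family,
    alkanes = vapply(seq_len(count), alkane_smiles, character(1)),
    alcohols = vapply(seq_len(count), function(n) paste0(alkane_smiles(n), "O"),
                      character(1)),
    mixed = {
      pool <- c(
        vapply(1:8, alkane_smiles, character(1)),
        paste0(vapply(1:6, alkane_smiles, character(1)), "O"),
        "COC", "CCOC", "CCOCC", "COCC",
        "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1",
        "CC(C)C", "CC(C)O", "CC(C)CC", "C=C", "C=CC", "C#C"
      )
      with_seed(seed, sample(pool, count, replace = TRUE))
    }
  )
  new_batch_input(entries, "inline")
}

#' Write a fixture batch to a CSV file
#'
#' Convenience wrapper producing a file consumable by [read_batch_csv()] and
#' the CLI's `--csv` flag.
#'
#' @inheritParams batch_fixture
#' @param path Output CSV path (one SMILES per row, no header).
#' @return `path`, invisibly.
#' @export
write_fixture_csv <- function(path, count, family = "mixed", seed = 0L) {
  batch <- batch_fixture(count, family, seed)
  writeLines(as.character(batch), path)
  invisible(path)
}

# Run an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. Keeps fixture/embedding
# determinism independent of the surrounding session.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
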