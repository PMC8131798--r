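#' Construct and validate a pedigree
#'
#' A pedigree is an acyclic parent map with mandatory sex labels. Individuals
#' whose parents are both unknown are founders and are assumed unrelated and
#' non-inbred. One-known-parent entries are permitted; the unknown side
#' contributes nothing to relatedness. On construction the pedigree is
#' validated and topologically sorted so that every parent precedes its
#' offspring, which is the order all relationship computations rely on.
#'
#' @param id character vector of unique individual identifiers.
#' @param dam,sire character vectors of parent identifiers; `NA` (or any token
#'   in `na_strings` when reading from file) marks an unknown parent.
#' @param sex character vector, `"female"` or `"male"` (abbreviations `f`/`m`
#'   and `F`/`M` are accepted). Mandatory for every individual: the sex-specific
#'   model cannot be built without it.
#' @param generation optional character vector (`"parental"`/`"offspring"`);
#'   inferred from parent knowledge when missing (founders are parental).
#' @return An object of class `"pedigree"`: a data frame with columns
#'   `id`, `dam`, `sire`, `sex`, `generation`, rows in topological order,
#'   plus integer parent indices in attributes.
#' @examples
#' ped <- pedigree(id = c("d", "s", "o"),
#'                 dam = c(NA, NA, "d"), sire = c(NA, NA, "s"),
#'                 sex = c("female", "male", "female"))
#' ped
#' @export
pedigree <- function(id, dam, sire, sex, generation = NULL) {
  id <- as.character(id); dam <- as.character(dam); sire <- as.character(sire)
  n <- length(id)
  stopifnot(length(dam) == n, length(sire) == n, length(sex) == n)
  if (anyNA(id) || any(id == "")) stop("missing individual id")
  if (anyDuplicated(id)) {
    stop("duplicate id in pedigree: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sex <- normalize_sex(sex)

  dam[!is.na(dam) & dam == ""] <- NA
  sire[!is.na(sire) & sire == ""] <- NA
  named_parents <- unique(c(dam[!is.na(dam)], sire[!is.na(sire)]))
  missing_par <- setdiff(named_parents, id)
  if (length(missing_par)) {
    stop("parents not present as individuals: ", paste(missing_par, collapse = ", "))
  }
  both <- intersect(unique(dam[!is.na(dam)]), unique(sire[!is.na(sire)]))
  if (length(both)) {
    stop("id used as both dam and sire: ", paste(both, collapse = ", "))
  }
  di <- match(dam, id); si <- match(sire, id)
  bad_dam <- !is.na(di) & sex[di] != "female"
  if (any(bad_dam)) stop("dam is not female: ", paste(unique(dam[bad_dam]), collapse = ", "))
  bad_sire <- !is.na(si) & sex[si] != "male"
  if (any(bad_sire)) stop("sire is not male: ", paste(unique(sire[bad_sire]), collapse = ", "))

  ord <- topo_order(di, si, id)
  id <- id[ord]; dam <- dam[ord]; sire <- sire[ord]; sex <- sex[ord]
  di <- match(dam, id); si <- match(sire, id)

  if (is.null(generation)) {
    generation <- ifelse(is.na(di) & is.na(si), "parental", "offspring")
  } else {
    generation <- as.character(generation)[ord]
    if (!all(generation %in% c("parental", "offspring"))) {
      stop("generation must be 'parental' or 'offspring'")
    }
  }

  out <- data.frame(id = id, dam = dam, sire = sire, sex = sex,
                    generation = generation, stringsAsFactors = FALSE)
  attr(out, "dam_idx") <- di
  attr(out, "sire_idx") <- si
  class(out) <- c("pedigree", "data.frame")
  out
}

normalize_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  sex[sex == "f"] <- "female"
  sex[sex == "m"] <- "male"
  if (anyNA(sex) || !all(sex %in% c("female", "male"))) {
    bad <- unique(sex[is.na(sex) | !sex %in% c("female", "male")])
    stop("unknown sex code: ", paste(bad, collapse = ", "),
         " (sex is mandatory; use 'female'/'male' or 'f'/'m')")
  }
  sex
}

# Kahn's algorithm; errors on cycles (an individual that is its own ancestor).
topo_order <- function(di, si, id) {
  n <- length(id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(di[i], si[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  # stable: founders in input order, then by release order
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    stop("cycle detected in pedigree involving: ",
         paste(id[setdiff(seq_len(n), ord)], collapse = ", "))
  }
  ord
}

#' Read a pedigree from a delimited file
#'
#' Expects a header row with columns `id`, `dam`, `sire`, `sex` and optionally
#' `generation`. The field delimiter (comma or tab) is autodetected from the
#' header line. Unknown parents may be encoded by any token in `na_strings`.
#' Reading is idempotent: the returned pedigree is identical no matter how the
#' rows are ordered in the file.
#'
#' @param path file path.
#' @param na_strings tokens interpreted as an unknown parent.
#' @return A [pedigree()] object, topologically sorted.
#' @export
read_pedigree <- function(path, na_strings = c("NA", "")) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           na.strings = na_strings, stringsAsFactors = FALSE,
                           comment.char = "")
  need <- c("id", "dam", "sire", "sex")
  if (!all(need %in% names(tab))) {
    stop("pedigree file must have columns id, dam, sire, sex; found: ",
         paste(names(tab), collapse = ", "))
  }
  pedigree(tab$id, tab$dam, tab$sire, tab$sex,
           generation = if ("generation" %in% names(tab)) tab$generation else NULL)
}

#' Write a pedigree to a delimited file
#' @param ped a [pedigree()] object.
#' @param path output path; tab-separated with `NA` for unknown parents.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @method print pedigree
#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(is.na(attr(x, "dam_idx")) & is.na(attr(x, "sire_idx")))
  cat("Pedigree:", nrow(x), "individuals (", nf, "founders,",
      sum(x$sex == "female"), "female /", sum(x$sex == "male"), "male )\n")
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
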