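# Pedigree container and pedigree algebra.
#
# A pedigree is stored as a data.frame (one row per individual) carrying the
# directed parent -> child graph implicitly through the father/mother columns.
# Sex is coded "M"/"F"/"U"; unknown parents and unknown birth years are NA.

#' Construct a pedigree
#'
#' Builds and validates a pedigree object from per-individual vectors. The
#' pedigree is a directed acyclic graph: each edge runs from a parent to a
#' child via the `father`/`mother` columns.
#'
#' @param id Character vector of unique individual identifiers.
#' @param father,mother Character vectors of parent ids; `NA`, `""` or `"0"`
#'   denote an unknown parent.
#' @param sex Character vector, one of `"M"`, `"F"`, `"U"` (also accepts
#'   `1`/`2`, `"male"`/`"female"` spellings).
#' @param birth_year Integer vector of birth years, `NA` if unknown.
#' @param sequenced Logical vector flagging individuals selected for
#'   sequencing.
#'
#' @return An object of class `pedigree` (a data.frame with columns `id`,
#'   `father`, `mother`, `sex`, `birth_year`, `sequenced`).
#'
#' @details Validation enforces that referenced parents exist, that no
#'   individual is used both as a father and as a mother, that fathers are
#'   male and mothers female, that the graph is acyclic, and that a child's
#'   birth year (when known) strictly exceeds each known parent's.
#'
#' @examples
#' ped <- pedigree(
#'   id     = c("p1", "p2", "c1"),
#'   father = c(NA, NA, "p1"),
#'   mother = c(NA, NA, "p2"),
#'   sex    = c("M", "F", "F"),
#'   birth_year = c(1990, 1991, 2000)
#' )
#' n_founders(ped)
#' @export
pedigree <- function(id, father = NA, mother = NA, sex = "U",
                     birth_year = NA, sequenced = TRUE) {
  n <- length(id)
  df <- data.frame(
    id = as.character(id),
    father = normalize_parent(rep_len(as.character(father), n)),
    mother = normalize_parent(rep_len(as.character(mother), n)),
    sex = normalize_sex(rep_len(as.character(sex), n)),
    birth_year = rep_len(as.integer(birth_year), n),
    sequenced = rep_len(as.logical(sequenced), n),
    stringsAsFactors = FALSE
  )
  validate_pedigree(df)
  class(df) <- c("pedigree", "data.frame")
  df
}

normalize_parent <- function(x) {
  x[!is.na(x) & (x == "0" | x == "" | x == ".")] <- NA_character_
  x
}

normalize_sex <- function(x) {
  out <- rep("U", length(x))
  x <- tolower(trimws(x))
  out[x %in% c("m", "male", "1")] <- "M"
  out[x %in% c("f", "female", "2")] <- "F"
  out
}

#' Validate pedigree structure
#'
#' Checks identifier uniqueness, parent existence, parent-sex consistency,
#' acyclicity and birth-year ordering. Called by all pedigree constructors;
#' exported so externally assembled data.frames can be checked too.
#'
#' @param ped A pedigree, or a data.frame with pedigree columns.
#' @return Invisibly `TRUE`; errors describe the first violation found,
#'   naming an offending individual.
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) {
    stop("duplicated individual id: ", ped$id[duplicated(ped$id)][1])
  }
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    bad <- !is.na(ref) & !(ref %in% ped$id)
    if (any(bad)) {
      stop("unknown ", col, " id '", ref[bad][1], "' referenced by '",
           ped$id[bad][1], "'")
    }
  }
  fathers <- stats::na.omit(unique(ped$father))
  mothers <- stats::na.omit(unique(ped$mother))
  both <- intersect(fathers, mothers)
  if (length(both) > 0) {
    stop("individual used as both father and mother: ", both[1])
  }
  sex_of <- ped$sex[match(fathers, ped$id)]
  if (any(sex_of == "F")) {
    stop("individual used as father but recorded female: ",
         fathers[sex_of == "F"][1])
  }
  sex_of <- ped$sex[match(mothers, ped$id)]
  if (any(sex_of == "M")) {
    stop("individual used as mother but recorded male: ",
         mothers[sex_of == "M"][1])
  }
  # acyclicity via Kahn's algorithm; any leftover node lies on a cycle
  depth <- ped_depth(ped, allow_cycle = TRUE)
  if (anyNA(depth)) {
    stop("pedigree cycle detected involving individual: ",
         sort(ped$id[is.na(depth)])[1])
  }
  # birth-year ordering child > parent where both known
  for (col in c("father", "mother")) {
    pidx <- match(ped[[col]], ped$id)
    ok <- is.na(pidx) | is.na(ped$birth_year) | is.na(ped$birth_year[pidx]) |
      ped$birth_year > ped$birth_year[pidx]
    if (!all(ok)) {
      stop("birth year of '", ped$id[!ok][1],
           "' is not greater than that of its ", col)
    }
  }
  invisible(TRUE)
}

# Generation depth: founders 0, child = 1 + max(parent depths). Returns NA
# for nodes on a cycle when allow_cycle = TRUE, otherwise callers stop first.
ped_depth <- function(ped, allow_cycle = FALSE) {
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  depth <- rep(NA_integer_, n)
  depth[is.na(fi) & is.na(mi)] <- 0L
  repeat {
    fd <- depth[fi]
    md <- depth[mi]
    fd[is.na(fi)] <- -1L
    md[is.na(mi)] <- -1L
    newd <- pmax(fd, md) + 1L
    ready <- is.na(depth) & !is.na(newd)
    if (!any(ready)) break
    depth[ready] <- newd[ready]
  }
  depth
}

#' Read a pedigree from a tab-delimited file
#'
#' The file dialect is a 6-column FAM-compatible superset: a header line and
#' columns `id`, `father`, `mother`, `sex`, `birth_year`, `sequenced`.
#' `"0"` or an empty field denotes an unknown parent; `birth_year` may be
#' empty; `sequenced` accepts `TRUE`/`FALSE`/`1`/`0` and defaults to `TRUE`
#' when the column is absent.
#'
#' @param path Path to the pedigree TSV file.
#' @return A validated [pedigree] object.
#' @seealso [write_pedigree()], [write_fam()]
#' @export
load_pedigree <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          na.strings = c("NA", ""))
  need <- c("id", "father", "mother", "sex", "birth_year")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("pedigree file lacks column(s): ", paste(miss, collapse = ", "))
  }
  seqd <- if ("sequenced" %in% names(df)) {
    df$sequenced %in% c("TRUE", "T", "1", "true")
  } else TRUE
  pedigree(
    id = df$id, father = df$father, mother = df$mother, sex = df$sex,
    birth_year = suppressWarnings(as.integer(df$birth_year)),
    sequenced = seqd
  )
}

#' Write a pedigree as tab-delimited text
#'
#' @param ped A [pedigree].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$father[is.na(out$father)] <- "0"
  out$mother[is.na(out$mother)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Export a pedigree in 6-column FAM layout
#'
#' Writes the conventional `family id father mother sex phenotype` layout
#' with a single constant family id, sex coded 1/2/0 and phenotype fixed
#' at -9.
#'
#' @param ped A [pedigree].
#' @param path Output file path.
#' @param family_id Constant family identifier used for every row.
#' @return Invisibly, `path`.
#' @export
write_fam <- function(ped, path, family_id = "FAM1") {
  sex_code <- c(M = 1L, F = 2L, U = 0L)[ped$sex]
  out <- data.frame(
    fid = family_id, id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = sex_code, pheno = -9L
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Founder predicate and count
#'
#' An individual is a founder when both parents are unknown.
#'
#' @param ped A [pedigree].
#' @return `is_founder()` a logical vector along `ped$id`; `n_founders()`
#'   the founder count.
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' @rdname is_founder
#' @export
n_founders <- function(ped) sum(is_founder(ped))

#' Immediate children of an individual
#'
#' Returns one-generation descendants of `id`, optionally restricted to
#' sequenced individuals. This is the descendant notion used by the greedy
#' coverage ranking.
#'
#' @param ped A [pedigree].
#' @param id Individual identifier.
#' @param sequenced_only If `TRUE`, intersect with the sequenced set.
#' @return Character vector of child ids (possibly empty), sorted.
#' @export
direct_children <- function(ped, id, sequenced_only = FALSE) {
  if (!(id %in% ped$id)) stop("unknown individual id: ", id)
  kids <- ped$id[(!is.na(ped$father) & ped$father == id) |
                 (!is.na(ped$mother) & ped$mother == id)]
  if (sequenced_only) kids <- kids[ped$sequenced[match(kids, ped$id)]]
  sort(kids)
}

#' Decompose a pedigree into nuclear units
#'
#' Breaks the pedigree into trios, parent-offspring duos and singletons for
#' unit-wise genotype refinement. Full sibships become distinct trios by
#' replicating parental information, and a parent with offspring from
#' several mates appears once per offspring; the replicate index records
#' how many units already contained that parent.
#'
#' @param ped A [pedigree].
#' @param sequenced_only If `TRUE` (default), only sequenced individuals
#'   form units, and a parent only joins a unit if itself sequenced.
#' @return A data.frame of class `nuclear_units` with columns `unit_id`,
#'   `kind` (`"trio"`, `"duo"`, `"singleton"`), `father`, `mother`, `child`,
#'   `father_rep`, `mother_rep`. Each eligible individual appears exactly
#'   once as `child`.
#' @export
decompose_units <- function(ped, sequenced_only = TRUE) {
  members <- if (sequenced_only) ped$id[ped$sequenced] else ped$id
  ord <- order(ped_depth(ped)[match(members, ped$id)], members)
  members <- members[ord]
  f_use <- integer(0)
  m_use <- integer(0)
  rows <- vector("list", length(members))
  for (k in seq_along(members)) {
    child <- members[k]
    i <- match(child, ped$id)
    fa <- ped$father[i]
    mo <- ped$mother[i]
    if (!is.na(fa) && !(fa %in% members)) fa <- NA_character_
    if (!is.na(mo) && !(mo %in% members)) mo <- NA_character_
    kind <- if (!is.na(fa) && !is.na(mo)) "trio"
            else if (!is.na(fa) || !is.na(mo)) "duo"
            else "singleton"
    f_rep <- m_rep <- NA_integer_
    if (!is.na(fa)) {
      f_use[fa] <- if (fa %in% names(f_use)) f_use[[fa]] + 1L else 1L
      f_rep <- f_use[[fa]]
    }
    if (!is.na(mo)) {
      m_use[mo] <- if (mo %in% names(m_use)) m_use[[mo]] + 1L else 1L
      m_rep <- m_use[[mo]]
    }
    rows[[k]] <- data.frame(
      unit_id = sprintf("u%04d", k), kind = kind,
      father = fa, mother = mo, child = child,
      father_rep = f_rep, mother_rep = m_rep,
      stringsAsFactors = FALSE
    )
  }
  units <- do.call(rbind, rows)
  if (is.null(units)) {
    units <- data.frame(unit_id = character(0), kind = character(0),
                        father = character(0), mother = character(0),
                        child = character(0), father_rep = integer(0),
                        mother_rep = integer(0))
  }
  class(units) <- c("nuclear_units", "data.frame")
  units
}

#' Pedigree kinship matrix
#'
#' Computes the kinship coefficient phi for every pair of pedigree members
#' by the standard recursion: founders are mutually unrelated,
#' `phi(i,i) = (1 + phi(father_i, mother_i)) / 2`, and for `i` processed
#' after `j` in generation order
#' `phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2`, with an unknown
#' parent contributing 0.
#'
#' @param ped A [pedigree].
#' @return A symmetric numeric matrix with dimnames `ped$id`.
#' @examples
#' ped <- pedigree(c("a", "b", "c"), c(NA, NA, "a"), c(NA, NA, "b"),
#'                 sex = c("M", "F", "U"))
#' kinship_matrix(ped)["a", "c"]  # 0.25
#' @export
kinship_matrix <- function(ped) {
  ids <- ped$id
  ord <- order(ped_depth(ped), ids)
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  for (k in seq_len(n)) {
    i <- ord[k]
    f <- fi[i]
    m <- mi[i]
    phi_fm <- if (!is.na(f) && !is.na(m)) phi[f, m] else 0
    phi[i, i] <- 0.5 * (1 + phi_fm)
    if (k > 1) {
      prev <- ord[seq_len(k - 1)]
      pf <- if (!is.na(f)) phi[f, prev] else 0
      pm <- if (!is.na(m)) phi[m, prev] else 0
      v <- 0.5 * (pf + pm)
      phi[i, prev] <- v
      phi[prev, i] <- v
    }
  }
  phi
}

#' Kinship coefficient of a pair
#'
#' @param ped A [pedigree].
#' @param id1,id2 Individual identifiers.
#' @param phi Optional precomputed [kinship_matrix()] to avoid recomputation.
#' @return The kinship coefficient, a number in `[0, 1]`.
#' @export
pedigree_kinship <- function(ped, id1, id2, phi = NULL) {
  for (id in c(id1, id2)) {
    if (!(id %in% ped$id)) stop("unknown individual id: ", id)
  }
  if (is.null(phi)) phi <- kinship_matrix(ped)
  unname(phi[id1, id2])
}
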