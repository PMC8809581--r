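#' Read flock observations from a delimited file
#'
#' Reads gambit-of-the-group flock observations in either *long* format
#' (one row per individual sighting, columns `flock_id`, `individual_id`
#' and optionally `site`, `date`) or *wide* group-by-individual format
#' (one row per flock, first column `flock_id` when
#' `flock_id_column = TRUE`, remaining columns one per individual with
#' binary 0/1 membership cells).
#'
#' Each returned row records one individual seen in one flock; a flock is a
#' spatial association of birds sampled as a unit, with repeated scans of the
#' same flock already collapsed upstream to a single membership record.
#'
#' @param path Path to a delimited text file (comma-separated).
#' @param format `"long"` or `"wide"`.
#' @param flock_id_column For wide files, whether the first column holds the
#'   flock id (`TRUE`, default) or rows are anonymous flocks.
#' @return A tibble with columns `flock_id`, `individual_id` and, when
#'   present in the input, `site` and `date`. Ids are kept verbatim.
#' @seealso [build_gbi()], [write_flock_observations()]
#' @export
read_flock_observations <- function(path, format = c("long", "wide"),
                                    flock_id_column = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("observation file not found: ", path, call. = FALSE)
  }
  if (format == "long") {
    dat <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    need <- c("flock_id", "individual_id")
    missing_cols <- setdiff(need, names(dat))
    if (length(missing_cols) > 0) {
      stop("long-format file lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    bad <- which(is.na(dat$flock_id) | is.na(dat$individual_id) |
                   dat$flock_id == "" | dat$individual_id == "")
    if (length(bad) > 0) {
      # +1 for the header line so the message points at the file line
      stop("malformed observation row at line ", bad[1] + 1L,
           ": missing flock_id or individual_id", call. = FALSE)
    }
    dup <- duplicated(dat[, c("flock_id", "individual_id")])
    if (any(dup)) {
      stop("duplicate individual within one flock at line ",
           which(dup)[1] + 1L, call. = FALSE)
    }
    keep <- intersect(c("flock_id", "individual_id", "site", "date"), names(dat))
    tibble::as_tibble(dat[, keep])
  } else {
    dat <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (flock_id_column) {
      flock_ids <- dat[[1]]
      cells <- dat[, -1, drop = FALSE]
    } else {
      flock_ids <- sprintf("flock_%d", seq_len(nrow(dat)))
      cells <- dat
    }
    mat <- as.matrix(cells)
    ok <- mat %in% c("0", "1")
    if (!all(ok)) {
      first <- which(!ok)[1]
      rr <- (first - 1L) %% nrow(mat) + 1L
      cc <- (first - 1L) %/% nrow(mat) + 1L
      stop("non-binary cell '", mat[rr, cc], "' at line ", rr + 1L,
           " (individual ", colnames(cells)[cc], ")", call. = FALSE)
    }
    storage.mode(mat) <- "integer"
    idx <- which(mat == 1L, arr.ind = TRUE)
    tibble::tibble(
      flock_id = flock_ids[idx[, 1]],
      individual_id = colnames(cells)[idx[, 2]]
    ) |>
      dplyr::arrange(match(.data$flock_id, flock_ids), .data$individual_id)
  }
}

#' Write flock observations to CSV
#'
#' Inverse of [read_flock_observations()]; round-trips a group-by-individual
#' matrix exactly.
#'
#' @param observations Long tibble as returned by [read_flock_observations()].
#' @param path Output file path.
#' @param format `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_flock_observations <- function(observations, path,
                                     format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    readr::write_csv(observations, path, progress = FALSE)
  } else {
    gbi <- build_gbi(observations)
    wide <- tibble::as_tibble(as.data.frame(gbi, check.names = FALSE))
    wide <- dplyr::bind_cols(tibble::tibble(flock_id = rownames(gbi)), wide)
    readr::write_csv(wide, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a node attribute table
#'
#' @param path CSV with columns `id`, `species` and optionally `site`.
#' @return A tibble with columns `id`, `species`, `site`.
#' @export
read_attributes <- function(path) {
  dat <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("id", "species")
  if (!all(need %in% names(dat))) {
    stop("attribute file needs columns id, species", call. = FALSE)
  }
  if (anyDuplicated(dat$id)) {
    stop("duplicate id in attribute table: ",
         dat$id[duplicated(dat$id)][1], call. = FALSE)
  }
  if (!"site" %in% names(dat)) dat$site <- NA_character_
  tibble::as_tibble(dat[, c("id", "species", "site")])
}

#' Build a group-by-individual (GBI) matrix
#'
#' Converts long observations into the binary flock-by-individual incidence
#' matrix that the association index and the datastream permutation operate
#' on. Under the gambit of the group, every pair of individuals sharing a row
#' is taken to be associated.
#'
#' @param observations Long tibble with columns `flock_id`, `individual_id`.
#' @return Integer matrix; rows are flocks (input order of first appearance),
#'   columns are individuals in lexicographic id order. Row sums are flock
#'   sizes, column sums are per-individual sighting counts.
#' @export
build_gbi <- function(observations) {
  if (nrow(observations) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = 0))
  }
  flocks <- unique(observations$flock_id)
  inds <- sort(unique(observations$individual_id))
  gbi <- matrix(0L, nrow = length(flocks), ncol = length(inds),
                dimnames = list(flocks, inds))
  gbi[cbind(match(observations$flock_id, flocks),
            match(observations$individual_id, inds))] <- 1L
  gbi
}

#' Filter transient individuals from a GBI matrix
#'
#' Drops individuals sighted fewer than `min_sightings` times (transients
#' weaken association estimates) and any explicitly excluded ids (e.g. birds
#' banded too late in the season for their sightings to be complete), then
#' drops flocks left with no members. Filtering is applied once, not
#' iterated: a flock reduced to a single member is kept, since that sighting
#' still counts in the denominator of the Simple Ratio Index for its member.
#'
#' @param gbi GBI matrix from [build_gbi()].
#' @param min_sightings Minimum sighting count to retain an individual.
#' @param exclude_ids Character vector of individual ids to drop regardless
#'   of sighting count.
#' @return Filtered GBI matrix.
#' @export
filter_individuals <- function(gbi, min_sightings = 3, exclude_ids = character()) {
  stopifnot(min_sightings >= 1)
  if (ncol(gbi) == 0) return(gbi)
  keep <- colSums(gbi) >= min_sightings & !(colnames(gbi) %in% exclude_ids)
  out <- gbi[, keep, drop = FALSE]
  out[rowSums(out) > 0, , drop = FALSE]
}

#' Read a square association matrix as a network
#'
#' Reads a symmetric association-index matrix (row and column headers are
#' individual ids, cells are index values in \[0, 1\]) and converts it to an
#' association network. Asymmetries within 1e-9 are averaged away; larger
#' asymmetry, non-square shape, missing cells, or values outside \[0, 1\] are
#' errors.
#'
#' @param path CSV path; first column holds row ids.
#' @param attributes Optional attribute tibble (`id`, `species`, `site`).
#' @return A `flock_network` object.
#' @export
read_association_matrix <- function(path, attributes = NULL) {
  dat <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE)
  ids <- as.character(dat[[1]])
  mat <- as.matrix(dat[, -1, drop = FALSE])
  if (nrow(mat) != ncol(mat)) {
    stop("association matrix is not square: ", nrow(mat), " x ", ncol(mat),
         call. = FALSE)
  }
  if (!identical(ids, colnames(mat))) {
    stop("row and column headers of the association matrix differ", call. = FALSE)
  }
  if (anyNA(mat)) stop("association matrix contains missing cells", call. = FALSE)
  storage.mode(mat) <- "double"
  asym <- max(abs(mat - t(mat)))
  if (asym > 1e-9) {
    stop("association matrix is asymmetric (max deviation ", signif(asym, 3),
         ")", call. = FALSE)
  }
  mat <- (mat + t(mat)) / 2
  if (any(mat < 0) || any(mat > 1)) {
    stop("association index values must lie in [0, 1]", call. = FALSE)
  }
  dimnames(mat) <- list(ids, ids)
  network_from_matrix(mat, attributes)
}
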