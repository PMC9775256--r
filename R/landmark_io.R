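# Landmark dataset containers and file I/O (TPS and wide CSV), plus
# antimere reflection.

#' Anatomical labels for the 30-landmark zygomatic scheme
#'
#' Names for the seven fixed landmarks (standard sutural definitions) and
#' generic labels \code{semi-8} ... \code{semi-30} for the 23 surface
#' semilandmarks.
#'
#' @param k number of landmarks; anatomical names are used only for
#'   \code{k = 30}.
#' @return character vector of length \code{k}.
#' @export
zygomatic_landmark_labels <- function(k = 30L) {
  if (k == 30L) {
    c("inferior zygotemporale", "superior zygotemporale",
      "frontomalare temporale", "frontomalare orbitale",
      "zygomaxillare orbitale", "inferior zygomaxillare",
      "inferior zygosphenoid",
      paste0("semi-", 8:30))
  } else {
    paste0("lm-", seq_len(k))
  }
}

#' Landmark roles for the 30-landmark zygomatic scheme
#'
#' @param k number of landmarks.
#' @param n_fixed number of leading fixed landmarks (default 7).
#' @return character vector with values \code{"fixed"} or
#'   \code{"surface_semilandmark"}.
#' @export
zygomatic_landmark_roles <- function(k = 30L, n_fixed = 7L) {
  stopifnot(n_fixed <= k)
  c(rep("fixed", n_fixed), rep("surface_semilandmark", k - n_fixed))
}

#' Construct a single landmark configuration
#'
#' @param specimen_id character scalar.
#' @param coords numeric \code{k x 3} matrix of finite coordinates.
#' @param roles per-landmark role, \code{"fixed"} or
#'   \code{"surface_semilandmark"}; recycled if scalar.
#' @param population,sex,side specimen metadata strings; \code{side} is one of
#'   \code{"left"}, \code{"right"}, \code{"unknown"}.
#' @return object of class \code{landmark_config}.
#' @export
landmark_config <- function(specimen_id, coords,
                            roles = "fixed",
                            population = "unknown", sex = "unknown",
                            side = "unknown") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be a k x 3 matrix")
  if (!all(is.finite(coords))) {
    stop("non-finite coordinates in specimen '", specimen_id,
         "'; missingness must be represented via damaged_configuration()")
  }
  if (length(roles) == 1L) roles <- rep(roles, nrow(coords))
  if (length(roles) != nrow(coords)) stop("roles length must equal k")
  if (!all(roles %in% c("fixed", "surface_semilandmark"))) {
    stop("roles must be 'fixed' or 'surface_semilandmark'")
  }
  side <- match.arg(side, c("left", "right", "unknown"))
  structure(list(specimen_id = as.character(specimen_id), coords = coords,
                 roles = roles, population = as.character(population),
                 sex = as.character(sex), side = side),
            class = "landmark_config")
}

#' Construct a landmark dataset
#'
#' @param coords numeric \code{k x 3 x n} array, third dimension named by
#'   specimen id (or ids supplied via \code{meta}).
#' @param roles per-landmark roles shared by all members.
#' @param meta data frame with columns \code{specimen_id}, \code{population},
#'   \code{sex}, \code{side} (missing columns are filled with
#'   \code{"unknown"}).
#' @param labels landmark names (length k); defaults to the zygomatic scheme.
#' @return object of class \code{landmark_dataset}.
#' @export
landmark_dataset <- function(coords, roles = NULL, meta = NULL, labels = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be a k x 3 x n array")
  }
  k <- dim(coords)[1]; n <- dim(coords)[3]
  if (n < 1L) stop("empty dataset: no configurations")
  if (!all(is.finite(coords))) stop("non-finite coordinates in dataset")
  roles <- roles %||% zygomatic_landmark_roles(k, min(7L, k))
  if (length(roles) != k) stop("roles length must equal k")
  labels <- labels %||% zygomatic_landmark_labels(k)
  if (length(labels) != k) stop("labels length must equal k")
  ids <- dimnames(coords)[[3]] %||% meta$specimen_id %||%
    sprintf("spec_%03d", seq_len(n))
  if (anyDuplicated(ids)) stop("specimen ids must be unique")
  if (is.null(meta)) {
    meta <- data.frame(specimen_id = ids, population = "unknown",
                       sex = "unknown", side = "unknown",
                       stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    meta$specimen_id <- as.character(meta$specimen_id %||% ids)
    for (col in c("population", "sex", "side")) {
      if (is.null(meta[[col]])) meta[[col]] <- "unknown"
      meta[[col]] <- as.character(meta[[col]])
    }
    meta <- meta[, c("specimen_id", "population", "sex", "side")]
    if (nrow(meta) != n) stop("meta must have one row per specimen")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"), meta$specimen_id)
  structure(list(coords = coords, roles = roles, labels = labels, meta = meta),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf("landmark_dataset: %d specimens, %d landmarks (%d fixed, %d semilandmarks)\n",
              n_specimens(x), n_landmarks(x),
              sum(x$roles == "fixed"),
              sum(x$roles == "surface_semilandmark")))
  pops <- table(x$meta$population)
  cat("populations:", paste(sprintf("%s=%d", names(pops), pops), collapse = ", "), "\n")
  invisible(x)
}

#' Number of specimens / landmarks in a dataset
#' @param ds a \code{landmark_dataset}.
#' @return integer count.
#' @export
n_specimens <- function(ds) dim(ds$coords)[3]

#' @rdname n_specimens
#' @export
n_landmarks <- function(ds) dim(ds$coords)[1]

#' Extract one configuration from a dataset
#' @param ds a \code{landmark_dataset}.
#' @param id specimen id (character) or index.
#' @return a \code{landmark_config}.
#' @export
get_configuration <- function(ds, id) {
  idx <- if (is.character(id)) match(id, ds$meta$specimen_id) else as.integer(id)
  if (is.na(idx) || idx < 1L || idx > n_specimens(ds)) {
    stop("unknown specimen: ", id)
  }
  m <- ds$meta[idx, ]
  landmark_config(m$specimen_id, ds$coords[, , idx], ds$roles,
                  m$population, m$sex, m$side)
}

#' Subset a dataset by specimen
#' @param ds a \code{landmark_dataset}.
#' @param ids character ids or integer indices to keep.
#' @return a \code{landmark_dataset}.
#' @export
subset_dataset <- function(ds, ids) {
  idx <- if (is.character(ids)) match(ids, ds$meta$specimen_id) else as.integer(ids)
  if (anyNA(idx)) stop("unknown specimen ids in subset")
  landmark_dataset(ds$coords[, , idx, drop = FALSE], ds$roles,
                   ds$meta[idx, , drop = FALSE], ds$labels)
}

#' Read a TPS landmark file
#'
#' Accepts the 3D dialect only: records begin with \code{LM3=<k>}, followed by
#' k lines of three numbers, then optional \code{SCALE=} (applied
#' multiplicatively), \code{IMAGE=} (ignored) and \code{ID=} lines.
#'
#' @param path file path.
#' @param roles,labels optional per-landmark roles/labels for the dataset.
#' @return a \code{landmark_dataset}.
#' @export
read_tps <- function(path, roles = NULL, labels = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty TPS file: ", path)
  starts <- grep("^LM3=", lines)
  if (length(starts) == 0L) stop("no LM3= records found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  configs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- suppressWarnings(as.integer(sub("^LM3=", "", block[1])))
    if (is.na(k) || k < 1L) stop("malformed LM3= line in record ", r)
    coord_lines <- grep("^[-+0-9.eE]", block[-1], value = TRUE)
    if (length(coord_lines) != k) {
      stop(sprintf("record %d: LM3=%d but %d coordinate lines present",
                   r, k, length(coord_lines)))
    }
    vals <- lapply(strsplit(coord_lines, "\\s+"), function(v) {
      x <- suppressWarnings(as.numeric(v))
      if (length(x) != 3L || anyNA(x)) {
        stop("record ", r, ": coordinate line is not three numbers")
      }
      x
    })
    coords <- do.call(rbind, vals)
    scale_line <- grep("^SCALE=", block, value = TRUE)
    if (length(scale_line)) {
      coords <- coords * as.numeric(sub("^SCALE=", "", scale_line[1]))
    }
    id_line <- grep("^ID=", block, value = TRUE)
    id <- if (length(id_line)) sub("^ID=", "", id_line[1]) else sprintf("spec_%03d", r)
    configs[[r]] <- list(id = id, coords = coords)
  }
  ks <- vapply(configs, function(cf) nrow(cf$coords), integer(1))
  if (length(unique(ks)) != 1L) {
    stop("mixed landmark counts across records: ",
         paste(unique(ks), collapse = ", "))
  }
  k <- ks[1]
  arr <- array(NA_real_, c(k, 3L, length(configs)))
  for (r in seq_along(configs)) arr[, , r] <- configs[[r]]$coords
  dimnames(arr)[[3]] <- vapply(configs, `[[`, character(1), "id")
  landmark_dataset(arr, roles = roles, labels = labels)
}

#' Write a TPS landmark file
#'
#' @param ds a \code{landmark_dataset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tps <- function(ds, path) {
  k <- n_landmarks(ds)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_specimens(ds))) {
    writeLines(sprintf("LM3=%d", k), con)
    m <- ds$coords[, , i]
    writeLines(apply(m, 1L, function(p) paste(sprintf("%.17g", p), collapse = " ")), con)
    writeLines(sprintf("ID=%s", ds$meta$specimen_id[i]), con)
  }
  invisible(path)
}

#' Read a wide-format landmark CSV
#'
#' Expected columns: \code{specimen_id}, optionally \code{population},
#' \code{sex}, \code{side}, then \code{lm<i>_x}, \code{lm<i>_y},
#' \code{lm<i>_z} for i = 1..k. When the metadata columns are absent, a JSON
#' sidecar keyed by specimen id may supply them.
#'
#' @param path CSV file path.
#' @param metadata optional path to a JSON sidecar:
#'   \code{{"<id>": {"population": ..., "sex": ..., "side": ...}, ...}}.
#' @param roles,labels optional per-landmark roles/labels.
#' @return a \code{landmark_dataset}.
#' @export
read_csv_wide <- function(path, metadata = NULL, roles = NULL, labels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty CSV: ", path)
  if (is.null(df$specimen_id)) stop("missing 'specimen_id' column")
  lm_cols <- grep("^lm[0-9]+_[xyz]$", names(df), value = TRUE)
  ks <- as.integer(sub("^lm([0-9]+)_[xyz]$", "\\1", lm_cols))
  if (length(ks) == 0L) stop("no lm<i>_{x,y,z} coordinate columns found")
  k <- max(ks)
  wanted <- as.vector(t(outer(seq_len(k), c("x", "y", "z"),
                              function(i, a) sprintf("lm%d_%s", i, a))))
  absent <- setdiff(wanted, names(df))
  if (length(absent)) {
    stop("missing coordinate column(s): ", paste(absent, collapse = ", "))
  }
  arr <- array(NA_real_, c(k, 3L, nrow(df)))
  for (i in seq_len(k)) {
    for (a in 1:3) {
      col <- sprintf("lm%d_%s", i, c("x", "y", "z")[a])
      v <- df[[col]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
        stop(sprintf("non-numeric value in column %s, row %d", col,
                     if (is.na(bad)) 1L else bad))
      }
      arr[i, a, ] <- v
    }
  }
  meta <- data.frame(specimen_id = as.character(df$specimen_id),
                     population = df$population %||% "unknown",
                     sex = df$sex %||% "unknown",
                     side = df$side %||% "unknown",
                     stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    side_info <- jsonlite::read_json(metadata)
    for (i in seq_len(nrow(meta))) {
      mi <- side_info[[meta$specimen_id[i]]]
      if (!is.null(mi)) {
        meta$population[i] <- mi$population %||% meta$population[i]
        meta$sex[i] <- mi$sex %||% meta$sex[i]
        meta$side[i] <- mi$side %||% meta$side[i]
      }
    }
  }
  dimnames(arr)[[3]] <- meta$specimen_id
  landmark_dataset(arr, roles = roles, meta = meta, labels = labels)
}

#' Write a wide-format landmark CSV
#'
#' @param ds a \code{landmark_dataset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_csv_wide <- function(ds, path) {
  k <- n_landmarks(ds)
  out <- ds$meta
  for (i in seq_len(k)) {
    for (a in 1:3) {
      out[[sprintf("lm%d_%s", i, c("x", "y", "z")[a])]] <- ds$coords[i, a, ]
    }
  }
  utils::write.csv(format(out, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reflect a configuration across a coordinate plane (antimere reflection)
#'
#' Mirrors the coordinates by negating one axis and flips the side flag.
#' Landmark order is unchanged: the zygomatic landmark scheme is
#' side-symmetric, so no relabelling is required.
#'
#' @param config a \code{landmark_config}.
#' @param axis normal axis of the mirror plane: \code{"x"} (default),
#'   \code{"y"} or \code{"z"}. Arbitrary under subsequent Procrustes
#'   alignment.
#' @return the reflected \code{landmark_config}.
#' @export
reflect_configuration <- function(config, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  coords <- config$coords
  coords[, ax] <- -coords[, ax]
  side <- switch(config$side, left = "right", right = "left", "unknown")
  landmark_config(config$specimen_id, coords, config$roles,
                  config$population, config$sex, side)
}
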