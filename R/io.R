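# Readers and writers for the mesh and table formats the pipeline uses.
# Vertex indices are 0-based in every file schema (FreeSurfer convention)
# and 1-based in memory; numeric CSV output is written at full %.17g
# precision so downstream fits reproduce bit-for-bit.

#' Read a triangulated surface from OFF, PLY or FreeSurfer binary
#'
#' Format is auto-detected from the file magic ("OFF", "ply", or the
#' FreeSurfer triangle-file magic 0xFFFFFE) unless a hint is given.  PLY is
#' supported in ascii and binary little-endian flavours.
#'
#' @param path file path.
#' @param format "auto" (default), "off", "ply" or "freesurfer".
#' @return a \code{triangulated_surface}.
#' @export
read_surface <- function(path, format = c("auto", "off", "ply", "freesurfer")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 3L)
    format <- if (identical(rawToChar(magic), "ply")) "ply"
      else if (identical(rawToChar(magic), "OFF")) "off"
      else if (identical(as.integer(magic), c(255L, 255L, 254L))) "freesurfer"
      else stop("cannot detect mesh format of ", path,
                " (first bytes: ", paste(magic, collapse = " "), ")")
  }
  switch(format,
         off = read_off(path),
         ply = read_ply(path),
         freesurfer = read_freesurfer_surface(path))
}

read_off <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  toks <- scan(text = txt, what = character(), quiet = TRUE)
  if (length(toks) == 0 || toks[1] != "OFF")
    stop("not an OFF file (missing OFF header): ", path)
  toks <- toks[-1]
  if (length(toks) < 3) stop("truncated OFF header in ", path)
  nv <- as.integer(toks[1]); nf <- as.integer(toks[2])
  toks <- toks[-(1:3)]
  if (length(toks) < 3 * nv) stop("truncated OFF vertex block in ", path,
                                  ": expected ", 3 * nv, " coordinates")
  v <- matrix(as.numeric(toks[seq_len(3 * nv)]), ncol = 3, byrow = TRUE)
  toks <- toks[-seq_len(3 * nv)]
  f <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    if (length(toks) < 1) stop("truncated OFF face block in ", path,
                               " at face ", i)
    k <- as.integer(toks[1])
    if (is.na(k) || k != 3L)
      stop("OFF face ", i, " in ", path, " is not a triangle (", toks[1],
           " vertices)")
    if (length(toks) < 1 + k) stop("truncated OFF face ", i, " in ", path)
    f[i, ] <- as.integer(toks[2:4]) + 1L
    toks <- toks[-(1:4)]
  }
  triangulated_surface(v, f, name = basename(path))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) stop("truncated PLY header in ", path)
    header <- c(header, line)
    if (line == "end_header") break
  }
  if (header[1] != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop("unsupported PLY format in ", path, ": ", fmt_line,
         " (ascii and binary_little_endian supported)")

  # element/property layout
  elements <- list()
  cur <- NULL
  for (line in header) {
    w <- strsplit(trimws(line), "\\s+")[[1]]
    if (w[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = w[2], count = as.integer(w[3]), props = list())
    } else if (w[1] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1L]] <-
        if (w[2] == "list") list(list = TRUE, count_type = w[3],
                                 item_type = w[4], name = w[5])
        else list(list = FALSE, type = w[2], name = w[3])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (!all(c("vertex", "face") %in% names(elements)))
    stop("PLY file ", path, " lacks vertex/face elements")

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  read_scalar <- function(type, n) {
    sz <- type_size[[type]]
    what <- if (type %in% c("float", "float32", "double", "float64"))
      "double" else "integer"
    readBin(con, what, n = n, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }

  ve <- elements$vertex
  fe <- elements$face
  if (binary) {
    nv <- ve$count
    vdat <- matrix(NA_real_, nv, length(ve$props))
    for (i in seq_len(nv))
      for (j in seq_along(ve$props))
        vdat[i, j] <- read_scalar(ve$props[[j]]$type, 1L)
    colnames(vdat) <- vapply(ve$props, `[[`, "", "name")
    f <- matrix(0L, fe$count, 3)
    for (i in seq_len(fe$count)) {
      lp <- fe$props[[1]]
      k <- read_scalar(lp$count_type, 1L)
      if (k != 3L) stop("PLY face ", i, " in ", path, " is not a triangle")
      f[i, ] <- read_scalar(lp$item_type, 3L)
      if (length(fe$props) > 1)
        for (j in 2:length(fe$props)) read_scalar(fe$props[[j]]$type, 1L)
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    if (length(body) < ve$count + fe$count)
      stop("truncated PLY body in ", path, ": expected ",
           ve$count + fe$count, " data lines, found ", length(body))
    vdat <- matrix(as.numeric(unlist(strsplit(trimws(body[seq_len(ve$count)]),
                                              "\\s+"))),
                   nrow = ve$count, byrow = TRUE)
    colnames(vdat) <- vapply(ve$props, `[[`, "", "name")
    flines <- strsplit(trimws(body[ve$count + seq_len(fe$count)]), "\\s+")
    f <- t(vapply(seq_along(flines), function(i) {
      w <- as.integer(flines[[i]])
      if (w[1] != 3L) stop("PLY face ", i, " in ", path, " is not a triangle")
      w[2:4]
    }, integer(3)))
  }
  v <- vdat[, c("x", "y", "z"), drop = FALSE]
  triangulated_surface(v, f + 1L, name = basename(path))
}

#' Read a FreeSurfer binary triangle surface
#'
#' The classic FreeSurfer surface format: 3-byte magic 0xFFFFFE, a comment
#' terminated by two newlines, big-endian vertex/face counts, float32
#' coordinates and int32 0-based triangles.
#'
#' @param path file path.
#' @return a \code{triangulated_surface}.
#' @export
read_freesurfer_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3L)
  if (!identical(as.integer(magic), c(255L, 255L, 254L)))
    stop("not a FreeSurfer triangle surface (magic ",
         paste(magic, collapse = " "), "): ", path)
  # comment line terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0) stop("truncated FreeSurfer surface header in ", path)
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1L, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1L, size = 4, endian = "big")
  v <- matrix(readBin(con, "double", 3L * nv, size = 4, endian = "big"),
              ncol = 3, byrow = TRUE)
  f <- matrix(readBin(con, "integer", 3L * nf, size = 4, endian = "big"),
              ncol = 3, byrow = TRUE)
  triangulated_surface(v, f + 1L, name = basename(path))
}

#' Read a FreeSurfer curv-style per-vertex file (e.g. thickness)
#'
#' New-format curv files: 3-byte magic 0xFFFFFF, big-endian counts, float32
#' values.
#'
#' @param path file path.
#' @return a \code{vertex_field}.
#' @export
read_freesurfer_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3L)
  if (!identical(as.integer(magic), c(255L, 255L, 255L)))
    stop("not a new-format FreeSurfer curv file: ", path)
  nv <- readBin(con, "integer", 1L, size = 4, endian = "big")
  readBin(con, "integer", 1L, size = 4, endian = "big")  # face count, unused
  vpv <- readBin(con, "integer", 1L, size = 4, endian = "big")
  if (vpv != 1L) stop("curv file with ", vpv, " values per vertex unsupported")
  vertex_field(readBin(con, "double", nv, size = 4, endian = "big"))
}

#' Write a surface to OFF or PLY
#'
#' @param surface a \code{triangulated_surface}.
#' @param path output path; format from extension unless given.
#' @param format "off" or "ply".
#' @param binary write binary little-endian PLY instead of ascii.
#' @return the path, invisibly.
#' @export
write_surface <- function(surface, path,
                          format = c("auto", "off", "ply"), binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     off = "off", ply = "ply",
                     stop("cannot infer format from extension of ", path))
  v <- surface$vertices
  f <- surface$triangles - 1L
  if (format == "off") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("ply",
                 if (binary) "format binary_little_endian 1.0"
                 else "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    if (binary) {
      for (i in seq_len(nrow(v)))
        writeBin(as.double(v[i, ]), con, size = 8, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(as.raw(3), con)
        writeBin(as.integer(f[i, ]), con, size = 4, endian = "little")
      }
    } else {
      writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
      writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
    }
  }
  invisible(path)
}

#' Read a dense per-vertex CSV (value or label)
#'
#' Schema: header \code{vertex_index,value} (scalar field) or
#' \code{vertex_index,label_id} (labels); indices 0-based and dense.
#' Rows may arrive in any order; duplicates and gaps are errors naming the
#' offending indices.
#'
#' @param path CSV path.
#' @return a \code{vertex_field} or \code{label_field}, by header.
#' @export
read_vertex_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"vertex_index" %in% names(d))
    stop("missing vertex_index column in ", path)
  kind <- if ("value" %in% names(d)) "value"
          else if ("label_id" %in% names(d)) "label_id"
          else stop("expected a value or label_id column in ", path)
  idx <- as.integer(d$vertex_index)
  if (anyDuplicated(idx))
    stop("duplicate vertex_index in ", path, ": ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "))
  expect <- 0:(nrow(d) - 1L)
  gaps <- setdiff(expect, idx)
  if (length(gaps))
    stop("vertex_index gaps in ", path, ": missing ",
         paste(utils::head(gaps, 10L), collapse = ", "))
  ord <- order(idx)
  if (kind == "value") vertex_field(d$value[ord])
  else label_field(d$label_id[ord])
}

# full-precision CSV writer: numerics via %.17g, everything else as-is
write_full_csv <- function(d, path) {
  fmt <- lapply(d, function(col)
    if (is.double(col)) sprintf("%.17g", col) else as.character(col))
  out <- do.call(paste, c(fmt, sep = ","))
  writeLines(c(paste(names(d), collapse = ","), out), path)
  invisible(path)
}

#' Write / read a per-partition morphology CSV
#'
#' Schema: \code{partition, A_t_mm2, A_e_mm2, T_mm, I_G_sr, n_vertices}
#' (full numeric precision).  The reader returns the in-memory column
#' names (\code{A_t}, \code{A_e}, \code{T}, \code{I_G},
#' \code{n_vertices_exposed}); extra columns round-trip unchanged.
#'
#' @param partitions data.frame as from \code{aggregate_partitions} or
#'   \code{group_to_lobes}.
#' @param path CSV path.
#' @return the path (writer) or the data.frame (reader).
#' @export
write_partition_csv <- function(partitions, path) {
  d <- data.frame(partition = partitions$partition,
                  A_t_mm2 = partitions$A_t,
                  A_e_mm2 = partitions$A_e,
                  T_mm = partitions$T,
                  I_G_sr = partitions$I_G,
                  n_vertices = partitions$n_vertices_exposed %||%
                    rep(NA_integer_, nrow(partitions)),
                  stringsAsFactors = FALSE)
  extra <- setdiff(names(partitions),
                   c("partition", "A_t", "A_e", "T", "I_G",
                     "n_vertices_exposed"))
  for (e in extra) d[[e]] <- partitions[[e]]
  write_full_csv(d, path)
}

#' @rdname write_partition_csv
#' @export
read_partition_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("partition", "A_t_mm2", "A_e_mm2", "T_mm", "I_G_sr")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("partition CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  rename <- c(A_t_mm2 = "A_t", A_e_mm2 = "A_e", T_mm = "T",
              I_G_sr = "I_G", n_vertices = "n_vertices_exposed")
  hit <- names(d) %in% names(rename)
  names(d)[hit] <- rename[names(d)[hit]]
  d
}

#' Write a corrected-morphology CSV
#'
#' Schema: \code{partition, A_e_prime, A_t_prime, T, x_prime, y_prime, K}
#' plus any grouping columns present (subject, hemisphere, age, group).
#'
#' @param corrected data.frame from \code{\link{correct_areas}}.
#' @param path CSV path.
#' @export
write_corrected_csv <- function(corrected, path) {
  keep <- intersect(c("subject", "hemisphere", "age", "sex", "group",
                      "partition", "A_e_prime", "A_t_prime", "T",
                      "x_prime", "y_prime", "K"),
                    names(corrected))
  write_full_csv(corrected[, keep, drop = FALSE], path)
}

#' Write a provenance JSON block
#'
#' Records every parameter needed to rerun a command identically: the
#' command name, parameters (including the seed) and package version.
#'
#' @param command command name.
#' @param params named list of parameters.
#' @param path output JSON path.
#' @export
write_provenance <- function(command, params, path) {
  jsonlite::write_json(
    list(command = command,
         parameters = params,
         package = "foldscale",
         version = as.character(utils::packageVersion("foldscale")),
         r_version = R.version.string),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}
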