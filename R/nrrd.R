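# Minimal NRRD support for 3D scalar volumes (no NRRD reader ships with the
# installed R stack). Covers the subset segmentation tools emit: detached or
# attached headers, raw / gzip encodings, common scalar types, `space
# directions` + `space origin` for the affine.

nrrd_types <- c(
  "uchar" = "integer", "unsigned char" = "integer", "uint8" = "integer",
  "short" = "integer", "int16" = "integer", "signed short" = "integer",
  "ushort" = "integer", "uint16" = "integer",
  "int" = "integer", "int32" = "integer", "signed int" = "integer",
  "float" = "double", "double" = "double"
)

nrrd_type_size <- c(
  "uchar" = 1, "unsigned char" = 1, "uint8" = 1,
  "short" = 2, "int16" = 2, "signed short" = 2,
  "ushort" = 2, "uint16" = 2,
  "int" = 4, "int32" = 4, "signed int" = 4,
  "float" = 4, "double" = 8
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1, warn = FALSE)
  if (!grepl("^NRRD000[0-9]$", magic)) abort(paste0("unreadable file: not NRRD: ", path))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) abort("unreadable file: truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- tolower(trimws(sub(":=?$", "", kv)))
    val <- trimws(sub("^[^:]+:=?", "", line))
    fields[[key]] <- val
  }
  need <- c("type", "dimension", "sizes", "encoding")
  if (!all(need %in% names(fields))) abort("unreadable file: incomplete NRRD header")
  if (as.integer(fields$dimension) != 3) abort("unreadable file: only 3D NRRD supported")
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- fields$type
  if (!type %in% names(nrrd_types)) abort(paste0("unreadable file: unsupported NRRD type ", type))
  endian <- fields[["endian"]] %||% "little"
  n <- prod(sizes)
  sz <- nrrd_type_size[[type]]
  signed <- !type %in% c("uchar", "unsigned char", "uint8", "ushort", "uint16")
  what <- if (nrrd_types[[type]] == "double") "numeric" else "integer"

  raw_con <- con
  datafile <- fields[["data file"]] %||% fields[["datafile"]]
  if (!is.null(datafile)) {
    raw_con <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  enc <- fields$encoding
  if (enc %in% c("raw")) {
    vals <- readBin(raw_con, what, n = n, size = sz, signed = signed,
                    endian = endian)
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(raw_con, "raw", n = file.size(path))
    bytes <- memDecompress(comp, type = "gzip")
    vals <- readBin(bytes, what, n = n, size = sz, signed = signed, endian = endian)
  } else {
    abort(paste0("unreadable file: unsupported NRRD encoding ", enc))
  }
  if (length(vals) < n) abort("unreadable file: truncated NRRD data")

  affine <- diag(4)
  if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    dm <- vapply(dirs, function(s) {
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
    }, numeric(3))
    affine[1:3, 1:3] <- dm   # columns are per-axis direction vectors
  }
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    affine[1:3, 1:3] <- diag(sp)
  }
  if (!is.null(fields[["space origin"]])) {
    affine[1:3, 4] <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  }
  list(data = array(vals, dim = sizes), affine = affine)
}

write_nrrd <- function(vol, path, encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  dirs <- vol$affine[1:3, 1:3]
  hdr <- c(
    "NRRD0004",
    "type: int",
    "dimension: 3",
    paste("sizes:", paste(dim(vol$voxels), collapse = " ")),
    "space: right-anterior-superior",
    paste0("space directions: ",
           paste(sprintf("(%g,%g,%g)", dirs[1, ], dirs[2, ], dirs[3, ]), collapse = " ")),
    sprintf("space origin: (%g,%g,%g)", vol$affine[1, 4], vol$affine[2, 4], vol$affine[3, 4]),
    "endian: little",
    paste("encoding:", if (encoding == "gzip") "gzip" else "raw"),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (encoding == "gzip") {
    tmp <- memCompress(writeBin(as.integer(vol$voxels), raw(), size = 4, endian = "little"),
                       type = "gzip")
    writeBin(tmp, con)
  } else {
    writeBin(as.integer(vol$voxels), con, size = 4, endian = "little")
  }
  invisible(path)
}
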