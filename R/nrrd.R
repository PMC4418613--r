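# Minimal NRRD support for 3D masks: attached header, raw or gzip encoding.
# Covers what segmentation tools typically emit for label maps; not a
# general NRRD implementation (no detached headers, no block types).

nrrd_types <- list(
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "uint8_t" = list(what = "integer", size = 1, signed = FALSE),
  "char" = list(what = "integer", size = 1, signed = TRUE),
  "int8" = list(what = "integer", size = 1, signed = TRUE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE),
  "float" = list(what = "numeric", size = 4, signed = TRUE),
  "double" = list(what = "numeric", size = 8, signed = TRUE)
)

read_nrrd <- function(path) {
  blob <- readBin(path, "raw", n = file.size(path))
  # header and data are separated by the first blank line
  sep <- which(blob[-length(blob)] == as.raw(10L) & blob[-1L] == as.raw(10L))
  if (!length(sep)) stop("truncated NRRD header: ", path, call. = FALSE)
  hdr_txt <- rawToChar(blob[seq_len(sep[1] - 1L)])
  data_raw <- blob[seq.int(sep[1] + 2L, length(blob))]
  lines <- strsplit(hdr_txt, "\n", fixed = TRUE)[[1]]
  if (!grepl("^NRRD000", lines[1]))
    stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  for (line in lines[-1]) {
    if (line == "" || grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+): ?(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(m[2])]] <- m[3]
  }
  dim_n <- as.integer(fields[["dimension"]])
  if (is.na(dim_n)) stop("NRRD header missing dimension", call. = FALSE)
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  type <- nrrd_types[[trimws(fields[["type"]])]]
  if (is.null(type))
    stop("unsupported NRRD type: ", fields[["type"]], call. = FALSE)
  encoding <- trimws(tolower(fields[["encoding"]] %||% "raw"))
  endian <- trimws(tolower(fields[["endian"]] %||% "little"))
  n <- prod(sizes)
  if (encoding == "raw") {
    vals <- readBin(data_raw, type$what, n = n, size = type$size,
                    signed = type$signed || type$size > 2, endian = endian)
  } else if (encoding %in% c("gzip", "gz")) {
    vals <- readBin(memDecompress(data_raw, type = "gzip"), type$what, n = n,
                    size = type$size, signed = type$signed || type$size > 2,
                    endian = endian)
  } else {
    stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  }
  if (length(vals) < n) stop("truncated NRRD data: ", path, call. = FALSE)
  spacing <- rep(NA_real_, dim_n)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(trimws(fields[["spacings"]]), "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    # row vectors like (1,0,0) (0,1,0) (0,0,2.5); spacing = vector norms
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    spacing <- vapply(vecs, function(v) {
      xs <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
      sqrt(sum(xs^2))
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    spacing <- rep(1, dim_n)
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]),
                                  ",")[[1]])
  }
  list(data = array(vals, sizes), spacing = spacing, origin = origin,
       space = fields[["space"]] %||% NA_character_)
}

write_nrrd <- function(arr, path, spacing = rep(1, 3), origin = c(0, 0, 0)) {
  con <- file(path, "wb")
  on.exit(close(con))
  storage <- if (all(arr >= 0 & arr <= 255) && all(arr == round(arr)))
    "uint8" else "double"
  hdr <- c(
    "NRRD0004",
    "# produced by thymoshape",
    paste0("type: ", storage),
    paste0("dimension: ", length(dim(arr))),
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dim(arr), collapse = " ")),
    paste0("space directions: ",
           paste(sprintf("(%s)", c(paste(c(spacing[1], 0, 0), collapse = ","),
                                   paste(c(0, spacing[2], 0), collapse = ","),
                                   paste(c(0, 0, spacing[3]), collapse = ","))),
                 collapse = " ")),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: gzip",
    paste0("space origin: (", paste(origin, collapse = ","), ")")
  )
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n\n")), con)
  if (storage == "uint8") {
    writeBin(memCompress(as.raw(as.integer(arr)), type = "gzip"), con)
  } else {
    tmp <- writeBin(as.numeric(arr), raw(), size = 8, endian = "little")
    writeBin(memCompress(tmp, type = "gzip"), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
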