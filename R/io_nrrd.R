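# Minimal NRRD0004 reader/writer. Supports the subset the pipeline emits and
# consumes: 3-D arrays, encodings "ascii"/"text" and "raw" (little endian),
# types double/float/int/short/uchar, spacings via "spacings" or
# "space directions" (diagonal), origin via "space origin". No gzip.

.nrrd_types <- list(
  double = list(what = "double", size = 8),
  float  = list(what = "double", size = 4),
  int    = list(what = "integer", size = 4),
  short  = list(what = "integer", size = 2),
  uchar  = list(what = "integer", size = 1)
)

read_nrrd <- function(path) {
  .assert(file.exists(path), "NRRD file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  .assert(grepl("^NRRD000", magic), "not an NRRD file: %s", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break        # header ran to EOF (detached header unsupported)
    if (line == "") break                # blank line separates header from data
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    .assert(length(kv) == 2L, "malformed NRRD header line: %s", line)
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  .assert(!is.null(fields$sizes) && !is.null(fields$type) && !is.null(fields$encoding),
          "NRRD header missing sizes/type/encoding")
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- fields$type
  if (type %in% c("float64", "double")) type <- "double"
  if (type == "float32") type <- "float"
  if (type %in% c("int32", "signed int")) type <- "int"
  .assert(type %in% names(.nrrd_types), "unsupported NRRD type: %s", fields$type)
  n <- prod(sizes)
  enc <- tolower(fields$encoding)
  if (enc %in% c("ascii", "text", "txt")) {
    txt <- readLines(con)
    vals <- as.numeric(strsplit(paste(txt, collapse = " "), "\\s+")[[1]])
    vals <- vals[!is.na(vals)]
  } else if (enc == "raw") {
    ti <- .nrrd_types[[type]]
    vals <- readBin(con, ti$what, n = n, size = ti$size, endian = "little")
  } else {
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  }
  .assert(length(vals) == n, "NRRD data length %d != prod(sizes) %d", length(vals), n)

  spacing <- rep(1, length(sizes))
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- vapply(dirs, function(d) {
      as.numeric(strsplit(gsub("[()]", "", d), ",")[[1]])
    }, numeric(length(sizes)))
    spacing <- sqrt(colSums(m^2))
  }
  origin <- rep(0, length(sizes))
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  }
  list(data = array(vals, dim = sizes), spacing = spacing, origin = origin,
       header = fields)
}

write_nrrd <- function(x, path, spacing = rep(1, length(dim(x))),
                       origin = rep(0, length(dim(x))),
                       encoding = c("ascii", "raw"), type = "double") {
  encoding <- match.arg(encoding)
  .assert(type %in% names(.nrrd_types), "unsupported NRRD type: %s", type)
  nd <- length(dim(x))
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    sprintf("dimension: %d", nd),
    sprintf("sizes: %s", paste(dim(x), collapse = " ")),
    sprintf("spacings: %s", paste(format(spacing, digits = 17), collapse = " ")),
    sprintf("space origin: (%s)", paste(format(origin, digits = 17), collapse = ",")),
    if (encoding == "raw") "endian: little",
    sprintf("encoding: %s", encoding),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (encoding == "ascii") {
    writeLines(paste(format(as.vector(x), digits = 17), collapse = " "), con)
  } else {
    ti <- .nrrd_types[[type]]
    vec <- if (ti$what == "integer") as.integer(x) else as.double(x)
    writeBin(vec, con, size = ti$size, endian = "little")
  }
  invisible(path)
}
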