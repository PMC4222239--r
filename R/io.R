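#' Standard-format I/O and the XML storage container
#'
#' FASTQ (Phred+33) and FASTA readers/writers, the versioned XML container
#' that binds message metadata to code parameters and fragment layout, and
#' the deterministic BMP fixture used by examples and tests.
#'
#' @name io
NULL

strip_cr <- function(lines) sub("\r$", "", lines)

#' Read a FASTQ file
#'
#' Phred+33 four-line records; CR/LF line endings are accepted. Mate
#' numbers are inferred from `/1` and `/2` id suffixes when present.
#' Malformed input is an error naming the offending line.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return Read `data.frame` with columns `id`, `bases`, `quals`, `mate`,
#'   `pair_id`.
#' @export
read_fastq <- function(path) {
  lines <- strip_cr(readLines(path))
  # trailing blank lines are tolerated
  while (length(lines) && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ: record starting at line ",
         4L * (length(lines) %/% 4L) + 1L, " is incomplete")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(id = character(0), bases = character(0),
                      quals = character(0), mate = integer(0),
                      pair_id = character(0), stringsAsFactors = FALSE))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ: line ", 4L * (bad[1] - 1L) + 1L,
         " does not start with '@'")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ: line ", 4L * (bad[1] - 1L) + 3L,
         " does not start with '+'")
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("malformed FASTQ: sequence/quality length mismatch at line ",
         4L * (bad[1] - 1L) + 2L)
  }
  id <- sub("^@", "", hdr)
  id <- sub("\\s.*$", "", id)
  mate <- ifelse(grepl("/1$", id), 1L, ifelse(grepl("/2$", id), 2L, NA_integer_))
  pair_id <- sub("/[12]$", "", id)
  data.frame(id = id, bases = toupper(seqs), quals = quals, mate = mate,
             pair_id = pair_id, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads Read `data.frame` (columns `id`, `bases`, `quals`).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads))
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    out[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$id)
    out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$bases
    out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
    out[seq(4L, by = 4L, length.out = nrow(reads))] <- reads$quals
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Multi-line records are joined; lowercase bases are normalized to
#' uppercase with a warning; an empty record id is an error.
#'
#' @param path Path to an uncompressed FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) {
    stop("FASTA record ", which(ids == "")[1], " has an empty id")
  }
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase bases normalized to uppercase")
    seqs <- toupper(seqs)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA
#'
#' Wraps sequence lines at 70 columns.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(names(seqs) != ""))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Write encoded blocks as FASTA
#'
#' One record per DNA information block, named `block_<address>`.
#'
#' @param blocks List of `dna_block` objects from [encode_message()].
#' @param path Output path.
#' @export
write_blocks_fasta <- function(blocks, path) {
  seqs <- vapply(blocks, `[[`, character(1), "bases")
  names(seqs) <- paste0("block_", vapply(blocks, `[[`, integer(1), "address"))
  write_fasta(seqs, path)
}

# ---- XML container -----------------------------------------------------------

.container_known_nodes <- c("message", "compression", "code", "layout")

#' Write a storage container as XML
#'
#' The container is a small versioned XML document that carries everything
#' needed to decode a message: payload metadata (length, CRC-32),
#' compression id, LDPC code parameters and the fragment layout. Unknown
#' elements found when reading are preserved verbatim and written back, so
#' third parties can extend the format without breaking round trips.
#'
#' @param container A [storage_container()].
#' @param path Output path.
#' @export
write_container <- function(container, path) {
  stopifnot(inherits(container, "storage_container"))
  doc <- xml2::xml_new_root("dnacodec", version = container$version)
  xml2::xml_add_child(doc, "message", name = container$name,
                      raw_length = as.character(container$raw_len),
                      crc32 = container$crc32)
  xml2::xml_add_child(doc, "compression", id = container$compression)
  xml2::xml_add_child(doc, "code",
                      n = as.character(container$code_n),
                      k = as.character(container$code_k),
                      col_weight = as.character(container$code_col_weight),
                      seed = as.character(container$code_seed))
  layout <- xml2::xml_add_child(doc, "layout",
                                n_fragments = as.character(container$n_fragments),
                                header_length = as.character(container$header_len))
  for (a in seq_len(container$n_fragments) - 1L) {
    xml2::xml_add_child(layout, "fragment", address = as.character(a),
                        pad_len = as.character(container$pad_len[a + 1L]))
  }
  for (node in container$extra) {
    xml2::xml_add_child(doc, xml2::xml_root(xml2::read_xml(node)))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

xml_attr_required <- function(node, attr, what) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) {
    stop("container validation: element <", what, "> is missing attribute '",
         attr, "'")
  }
  v
}

#' Read a storage container from XML
#'
#' Validation errors name the missing element or attribute. Elements not
#' part of the schema are preserved in `$extra`.
#'
#' @param path Path to a container XML file.
#' @return A [storage_container()].
#' @export
read_container <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "dnacodec") {
    stop("container validation: root element must be <dnacodec>")
  }
  version <- xml2::xml_attr(doc, "version")
  if (is.na(version)) stop("container validation: missing version attribute")
  if (version != .container_version) {
    stop("container version ", version, " is not supported (expected ",
         .container_version, ")")
  }
  need <- function(name) {
    node <- xml2::xml_find_first(doc, name)
    if (inherits(node, "xml_missing")) {
      stop("container validation: missing element <", name, ">")
    }
    node
  }
  msg <- need("message")
  comp <- need("compression")
  code <- need("code")
  layout <- need("layout")
  n_fragments <- as.integer(xml_attr_required(layout, "n_fragments", "layout"))
  frag_nodes <- xml2::xml_find_all(layout, "fragment")
  if (length(frag_nodes) != n_fragments) {
    stop("container validation: expected ", n_fragments,
         " <fragment> elements, found ", length(frag_nodes))
  }
  pad <- integer(n_fragments)
  for (fn in frag_nodes) {
    a <- as.integer(xml_attr_required(fn, "address", "fragment"))
    pad[a + 1L] <- as.integer(xml_attr_required(fn, "pad_len", "fragment"))
  }
  extra_nodes <- xml2::xml_children(doc)
  extra_nodes <- extra_nodes[!(xml2::xml_name(extra_nodes) %in% .container_known_nodes)]
  storage_container(
    name = xml_attr_required(msg, "name", "message"),
    raw_len = as.integer(xml_attr_required(msg, "raw_length", "message")),
    crc32 = xml_attr_required(msg, "crc32", "message"),
    compression = xml_attr_required(comp, "id", "compression"),
    n_fragments = n_fragments,
    code_n = as.integer(xml_attr_required(code, "n", "code")),
    code_k = as.integer(xml_attr_required(code, "k", "code")),
    code_col_weight = as.integer(xml_attr_required(code, "col_weight", "code")),
    code_seed = as.integer(xml_attr_required(code, "seed", "code")),
    header_len = as.integer(xml_attr_required(layout, "header_length", "layout")),
    pad_len = pad,
    extra = lapply(extra_nodes, function(n) as.character(n))
  )
}

# ---- fixture image -----------------------------------------------------------

le_bytes <- function(x, n) {
  as.raw((x %/% 256^(0:(n - 1))) %% 256)
}

#' Deterministic BMP test image
#'
#' A synthetic 30 x 20 pixel, 4-bit (16-color palette) BMP of exactly 438
#' bytes: 14-byte file header, 40-byte info header, 64-byte palette and
#' 320 bytes of pixel data (16-byte padded rows). The pixel pattern is a
#' fixed set of diagonal stripes, so the image compresses well. Repeated
#' calls are byte-identical.
#'
#' @return A `raw` vector of length 438.
#' @export
make_fixture_image <- function() {
  width <- 30L; height <- 20L
  row_bytes <- ((width * 4L + 31L) %/% 32L) * 4L   # 16
  data_size <- row_bytes * height                  # 320
  palette_size <- 16L * 4L                         # 64
  offset <- 14L + 40L + palette_size               # 118
  file_size <- offset + data_size                  # 438

  header <- c(charToRaw("BM"), le_bytes(file_size, 4L), raw(4L),
              le_bytes(offset, 4L))
  info <- c(le_bytes(40L, 4L), le_bytes(width, 4L), le_bytes(height, 4L),
            le_bytes(1L, 2L), le_bytes(4L, 2L), le_bytes(0L, 4L),
            le_bytes(data_size, 4L), le_bytes(2835L, 4L), le_bytes(2835L, 4L),
            le_bytes(16L, 4L), le_bytes(0L, 4L))
  # grayscale palette, BGRA quads
  palette <- as.raw(unlist(lapply(0:15, function(i) c(rep(i * 17L, 3L), 0L))))

  # diagonal stripes with a solid border
  pix <- outer(seq_len(height), seq_len(width),
               function(y, x) ((x + 2L * y) %/% 3L) %% 16L)
  pix[1, ] <- 15L; pix[height, ] <- 15L; pix[, 1] <- 15L; pix[, width] <- 15L
  rows <- lapply(rev(seq_len(height)), function(y) {  # bottom-up storage
    v <- pix[y, ]
    if (length(v) %% 2L == 1L) v <- c(v, 0L)
    packed <- as.raw(v[c(TRUE, FALSE)] * 16L + v[c(FALSE, TRUE)])
    c(packed, raw(row_bytes - length(packed)))
  })
  out <- c(header, info, palette, unlist(rows))
  stopifnot(length(out) == 438L)
  out
}
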