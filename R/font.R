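# Built-in 5x7 bitmap font for annotation labels. Each glyph is 7 rows of
# 5-bit bitmaps (MSB = left pixel). Uppercase letters, digits and a few
# symbols; lowercase input is folded to uppercase before lookup, unknown
# characters render as blanks. Avoids any dependency on a graphics device,
# keeping rendered images byte-deterministic.
FONT5X7 <- list(
  "A" = c(0x0E, 0x11, 0x11, 0x1F, 0x11, 0x11, 0x11),
  "B" = c(0x1E, 0x11, 0x11, 0x1E, 0x11, 0x11, 0x1E),
  "C" = c(0x0E, 0x11, 0x10, 0x10, 0x10, 0x11, 0x0E),
  "D" = c(0x1E, 0x11, 0x11, 0x11, 0x11, 0x11, 0x1E),
  "E" = c(0x1F, 0x10, 0x10, 0x1E, 0x10, 0x10, 0x1F),
  "F" = c(0x1F, 0x10, 0x10, 0x1E, 0x10, 0x10, 0x10),
  "G" = c(0x0E, 0x11, 0x10, 0x17, 0x11, 0x11, 0x0F),
  "H" = c(0x11, 0x11, 0x11, 0x1F, 0x11, 0x11, 0x11),
  "I" = c(0x0E, 0x04, 0x04, 0x04, 0x04, 0x04, 0x0E),
  "J" = c(0x07, 0x02, 0x02, 0x02, 0x02, 0x12, 0x0C),
  "K" = c(0x11, 0x12, 0x14, 0x18, 0x14, 0x12, 0x11),
  "L" = c(0x10, 0x10, 0x10, 0x10, 0x10, 0x10, 0x1F),
  "M" = c(0x11, 0x1B, 0x15, 0x15, 0x11, 0x11, 0x11),
  "N" = c(0x11, 0x19, 0x15, 0x13, 0x11, 0x11, 0x11),
  "O" = c(0x0E, 0x11, 0x11, 0x11, 0x11, 0x11, 0x0E),
  "P" = c(0x1E, 0x11, 0x11, 0x1E, 0x10, 0x10, 0x10),
  "Q" = c(0x0E, 0x11, 0x11, 0x11, 0x15, 0x12, 0x0D),
  "R" = c(0x1E, 0x11, 0x11, 0x1E, 0x14, 0x12, 0x11),
  "S" = c(0x0F, 0x10, 0x10, 0x0E, 0x01, 0x01, 0x1E),
  "T" = c(0x1F, 0x04, 0x04, 0x04, 0x04, 0x04, 0x04),
  "U" = c(0x11, 0x11, 0x11, 0x11, 0x11, 0x11, 0x0E),
  "V" = c(0x11, 0x11, 0x11, 0x11, 0x11, 0x0A, 0x04),
  "W" = c(0x11, 0x11, 0x11, 0x15, 0x15, 0x1B, 0x11),
  "X" = c(0x11, 0x11, 0x0A, 0x04, 0x0A, 0x11, 0x11),
  "Y" = c(0x11, 0x11, 0x0A, 0x04, 0x04, 0x04, 0x04),
  "Z" = c(0x1F, 0x01, 0x02, 0x04, 0x08, 0x10, 0x1F),
  "0" = c(0x0E, 0x11, 0x13, 0x15, 0x19, 0x11, 0x0E),
  "1" = c(0x04, 0x0C, 0x04, 0x04, 0x04, 0x04, 0x0E),
  "2" = c(0x0E, 0x11, 0x01, 0x06, 0x08, 0x10, 0x1F),
  "3" = c(0x1F, 0x02, 0x04, 0x02, 0x01, 0x11, 0x0E),
  "4" = c(0x02, 0x06, 0x0A, 0x12, 0x1F, 0x02, 0x02),
  "5" = c(0x1F, 0x10, 0x1E, 0x01, 0x01, 0x11, 0x0E),
  "6" = c(0x06, 0x08, 0x10, 0x1E, 0x11, 0x11, 0x0E),
  "7" = c(0x1F, 0x01, 0x02, 0x04, 0x08, 0x08, 0x08),
  "8" = c(0x0E, 0x11, 0x11, 0x0E, 0x11, 0x11, 0x0E),
  "9" = c(0x0E, 0x11, 0x11, 0x0F, 0x01, 0x02, 0x0C),
  " " = c(0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00),
  "-" = c(0x00, 0x00, 0x00, 0x1F, 0x00, 0x00, 0x00),
  "." = c(0x00, 0x00, 0x00, 0x00, 0x00, 0x0C, 0x0C),
  "_" = c(0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x1F),
  "(" = c(0x02, 0x04, 0x08, 0x08, 0x08, 0x04, 0x02),
  ")" = c(0x08, 0x04, 0x02, 0x02, 0x02, 0x04, 0x08),
  "/" = c(0x01, 0x01, 0x02, 0x04, 0x08, 0x10, 0x10)
)

# glyph bitmap as a 7x5 logical matrix, or NULL for unknown characters
font_glyph <- function(ch) {
  g <- FONT5X7[[toupper(ch)]]
  if (is.null(g)) return(NULL)
  t(vapply(g, function(row) as.logical(bitwAnd(row, c(16L, 8L, 4L, 2L, 1L))),
           logical(5)))
}
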