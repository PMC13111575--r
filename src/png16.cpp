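#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <vector>

using namespace Rcpp;

// Minimal 16-bit grayscale PNG encoder. The CRAN png package reads 16-bit
// PNGs but only writes 8-bit ones, so the high-bit-depth write path is
// provided here: one IHDR (bit depth 16, color type 0), a single IDAT with
// filter-0 scanlines deflated by zlib, and IEND.

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static void put_chunk(std::vector<unsigned char>& out, const char* type,
                      const unsigned char* data, size_t n) {
  put_u32(out, static_cast<uint32_t>(n));
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  if (n) out.insert(out.end(), data, data + n);
  uint32_t crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, static_cast<uInt>(n + 4));
  put_u32(out, crc);
}

// [[Rcpp::export(name = ".write_png16")]]
void write_png16(const IntegerMatrix& img, const std::string& path) {
  const int nr = img.nrow(), nc = img.ncol();
  // filter byte 0 per row, then big-endian 16-bit samples, row-major
  std::vector<unsigned char> raw;
  raw.reserve(static_cast<size_t>(nr) * (1 + 2 * nc));
  for (int j = 0; j < nr; ++j) {
    raw.push_back(0);
    for (int i = 0; i < nc; ++i) {
      int v = img(j, i);
      if (v < 0 || v > 65535) stop("pixel value out of 16-bit range");
      raw.push_back((v >> 8) & 0xff);
      raw.push_back(v & 0xff);
    }
  }
  uLongf bound = compressBound(static_cast<uLong>(raw.size()));
  std::vector<unsigned char> comp(bound);
  if (compress2(comp.data(), &bound, raw.data(),
                static_cast<uLong>(raw.size()), 6) != Z_OK)
    stop("zlib compression failed");
  comp.resize(bound);

  std::vector<unsigned char> out;
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  out.insert(out.end(), sig, sig + 8);
  unsigned char ihdr[13];
  uint32_t w = static_cast<uint32_t>(nc), h = static_cast<uint32_t>(nr);
  ihdr[0] = (w >> 24) & 0xff; ihdr[1] = (w >> 16) & 0xff;
  ihdr[2] = (w >> 8) & 0xff;  ihdr[3] = w & 0xff;
  ihdr[4] = (h >> 24) & 0xff; ihdr[5] = (h >> 16) & 0xff;
  ihdr[6] = (h >> 8) & 0xff;  ihdr[7] = h & 0xff;
  ihdr[8] = 16;  // bit depth
  ihdr[9] = 0;   // color type: grayscale
  ihdr[10] = 0; ihdr[11] = 0; ihdr[12] = 0;
  put_chunk(out, "IHDR", ihdr, 13);
  put_chunk(out, "IDAT", comp.data(), comp.size());
  put_chunk(out, "IEND", NULL, 0);

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  size_t written = std::fwrite(out.data(), 1, out.size(), f);
  std::fclose(f);
  if (written != out.size()) stop("short write to '%s'", path.c_str());
}
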