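// Minimal PNG codec (8-bit, non-interlaced) backed by system zlib.
// Decodes gray / gray+alpha / RGB / RGBA to an H x W x 3 integer array
// (alpha is dropped); encodes H x W x 3 as 8-bit RGB, filter type 0.
#include <Rcpp.h>
#include <zlib.h>
#include <cstring>
using namespace Rcpp;

static uint32_t be32(const unsigned char *p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

static void put_be32(std::vector<unsigned char> &v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

// [[Rcpp::export(name = ".png_decode")]]
IntegerVector png_decode(RawVector data) {
  const unsigned char *d = RAW(data);
  size_t n = data.size();
  static const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  if (n < 8 || std::memcmp(d, sig, 8) != 0)
    stop("not a PNG file (bad signature)");
  size_t pos = 8;
  uint32_t W = 0, H = 0;
  int bitdepth = 0, colortype = -1, interlace = 0;
  bool seen_ihdr = false, seen_iend = false;
  std::vector<unsigned char> idat;
  while (pos + 12 <= n) {
    uint32_t len = be32(d + pos);
    if (pos + 12 + (size_t)len > n) stop("truncated PNG chunk");
    const unsigned char *type = d + pos + 4;
    const unsigned char *body = d + pos + 8;
    if (!std::memcmp(type, "IHDR", 4)) {
      if (len != 13) stop("malformed IHDR");
      W = be32(body);
      H = be32(body + 4);
      bitdepth = body[8];
      colortype = body[9];
      interlace = body[12];
      seen_ihdr = true;
    } else if (!std::memcmp(type, "IDAT", 4)) {
      idat.insert(idat.end(), body, body + len);
    } else if (!std::memcmp(type, "IEND", 4)) {
      seen_iend = true;
      break;
    }
    pos += 12 + (size_t)len;
  }
  if (!seen_ihdr || !seen_iend || idat.empty())
    stop("truncated or malformed PNG");
  if (W < 1 || H < 1) stop("malformed PNG dimensions");
  if (bitdepth != 8) stop("unsupported PNG bit depth (only 8-bit)");
  if (interlace != 0) stop("interlaced PNG not supported");
  int ch;
  switch (colortype) {
    case 0: ch = 1; break;
    case 2: ch = 3; break;
    case 4: ch = 2; break;
    case 6: ch = 4; break;
    default: stop("unsupported PNG color type");
  }
  size_t stride = (size_t)W * ch;
  std::vector<unsigned char> raw((stride + 1) * H);
  uLongf rawlen = (uLongf)raw.size();
  int zrc = uncompress(raw.data(), &rawlen, idat.data(), (uLong)idat.size());
  if (zrc != Z_OK || rawlen != raw.size())
    stop("corrupt PNG pixel data");
  std::vector<unsigned char> img(stride * H);
  for (uint32_t y = 0; y < H; ++y) {
    int f = raw[y * (stride + 1)];
    const unsigned char *src = &raw[y * (stride + 1) + 1];
    unsigned char *cur = &img[y * stride];
    const unsigned char *up = y ? &img[(y - 1) * stride] : NULL;
    for (size_t x = 0; x < stride; ++x) {
      int a = x >= (size_t)ch ? cur[x - ch] : 0;
      int b = up ? up[x] : 0;
      int c = (up && x >= (size_t)ch) ? up[x - ch] : 0;
      int v = src[x];
      switch (f) {
        case 0: break;
        case 1: v += a; break;
        case 2: v += b; break;
        case 3: v += (a + b) / 2; break;
        case 4: {
          int p = a + b - c;
          int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
          v += (pa <= pb && pa <= pc) ? a : (pb <= pc ? b : c);
          break;
        }
        default: stop("corrupt PNG (invalid filter type)");
      }
      cur[x] = (unsigned char)(v & 0xff);
    }
  }
  IntegerVector out((R_xlen_t)H * W * 3);
  out.attr("dim") = IntegerVector::create((int)H, (int)W, 3);
  size_t plane = (size_t)H * W;
  for (uint32_t y = 0; y < H; ++y) {
    for (uint32_t x = 0; x < W; ++x) {
      const unsigned char *px = &img[y * stride + (size_t)x * ch];
      int r, g, b;
      if (ch <= 2) { r = g = b = px[0]; }
      else { r = px[0]; g = px[1]; b = px[2]; }
      size_t off = (size_t)y + (size_t)H * x;
      out[off] = r;
      out[off + plane] = g;
      out[off + 2 * plane] = b;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".png_encode")]]
RawVector png_encode(IntegerVector pixels) {
  IntegerVector dim = pixels.attr("dim");
  if (dim.size() != 3 || dim[2] != 3) stop("pixels must be an H x W x 3 array");
  uint32_t H = dim[0], W = dim[1];
  size_t plane = (size_t)H * W;
  size_t stride = (size_t)W * 3;
  std::vector<unsigned char> raw((stride + 1) * H);
  for (uint32_t y = 0; y < H; ++y) {
    raw[y * (stride + 1)] = 0;  // filter: none
    unsigned char *row = &raw[y * (stride + 1) + 1];
    for (uint32_t x = 0; x < W; ++x) {
      size_t off = (size_t)y + (size_t)H * x;
      row[3 * (size_t)x] = (unsigned char)pixels[off];
      row[3 * (size_t)x + 1] = (unsigned char)pixels[off + plane];
      row[3 * (size_t)x + 2] = (unsigned char)pixels[off + 2 * plane];
    }
  }
  uLongf bound = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(bound);
  if (compress2(comp.data(), &bound, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("zlib compression failed");
  comp.resize(bound);

  std::vector<unsigned char> out;
  static const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  out.insert(out.end(), sig, sig + 8);
  // IHDR
  std::vector<unsigned char> ihdr;
  const unsigned char ihdr_type[4] = {'I', 'H', 'D', 'R'};
  ihdr.insert(ihdr.end(), ihdr_type, ihdr_type + 4);
  put_be32(ihdr, W);
  put_be32(ihdr, H);
  ihdr.push_back(8);   // bit depth
  ihdr.push_back(2);   // color type: RGB
  ihdr.push_back(0);   // compression
  ihdr.push_back(0);   // filter
  ihdr.push_back(0);   // interlace
  put_be32(out, 13);
  out.insert(out.end(), ihdr.begin(), ihdr.end());
  put_be32(out, (uint32_t)crc32(0L, ihdr.data(), (uInt)ihdr.size()));
  // IDAT
  std::vector<unsigned char> idat;
  const unsigned char idat_type[4] = {'I', 'D', 'A', 'T'};
  idat.insert(idat.end(), idat_type, idat_type + 4);
  idat.insert(idat.end(), comp.begin(), comp.end());
  put_be32(out, (uint32_t)comp.size());
  out.insert(out.end(), idat.begin(), idat.end());
  put_be32(out, (uint32_t)crc32(0L, idat.data(), (uInt)idat.size()));
  // IEND
  const unsigned char iend_type[4] = {'I', 'E', 'N', 'D'};
  put_be32(out, 0);
  out.insert(out.end(), iend_type, iend_type + 4);
  put_be32(out, (uint32_t)crc32(0L, iend_type, 4));

  RawVector res(out.size());
  std::memcpy(RAW(res), out.data(), out.size());
  return res;
}
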