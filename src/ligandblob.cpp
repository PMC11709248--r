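#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// CRC-32 (IEEE 802.3, reflected), needed for the STORE-zip blob containers.
static uint32_t crc_table[256];
static bool crc_ready = false;

static void crc_init() {
  for (uint32_t n = 0; n < 256; ++n) {
    uint32_t c = n;
    for (int k = 0; k < 8; ++k)
      c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
    crc_table[n] = c;
  }
  crc_ready = true;
}

// [[Rcpp::export(name = ".crc32_raw")]]
double crc32_raw(RawVector x) {
  if (!crc_ready) crc_init();
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    c = crc_table[(c ^ x[i]) & 0xFFu] ^ (c >> 8);
  return static_cast<double>(c ^ 0xFFFFFFFFu);
}

// Label connected components of the nonzero voxels of a 3D grid.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Returns an integer vector of labels (0 = background), in the input's
// (column-major) linear order. Labels are assigned in scan order.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(NumericVector values, IntegerVector dim,
                               int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector labels(n, 0);

  // neighbor offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ord = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (values[start] == 0.0 || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = static_cast<int>(v % nx);
      int y = static_cast<int>((v / nx) % ny);
      int z = static_cast<int>(v / (static_cast<R_xlen_t>(nx) * ny));
      for (size_t k = 0; k < dxs.size(); ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + static_cast<R_xlen_t>(nx) * (yy + static_cast<R_xlen_t>(ny) * zz);
        if (values[w] != 0.0 && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}
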