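// Minimal HDF5 reader/writer for detector frame stacks.
//
// File layout (fixed by this package):
//   /frames    N x H x W, 32-bit signed integers (C row-major, h5py-compatible)
//   /mask      H x W, 8-bit unsigned, optional (1 = trusted)
//   /frame_ids N variable-length UTF-8 strings, optional
//   root attributes: beam_center_row, beam_center_col (double, 1-based),
//                    source_tag (string)

#include <Rcpp.h>
#include <hdf5.h>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct H5File {
  hid_t id;
  explicit H5File(hid_t id_) : id(id_) {}
  ~H5File() { if (id >= 0) H5Fclose(id); }
};

void write_string_attr(hid_t loc, const char* name, const std::string& value) {
  hid_t type = H5Tcopy(H5T_C_S1);
  H5Tset_size(type, value.empty() ? 1 : value.size());
  H5Tset_cset(type, H5T_CSET_UTF8);
  hid_t sp = H5Screate(H5S_SCALAR);
  hid_t att = H5Acreate2(loc, name, type, sp, H5P_DEFAULT, H5P_DEFAULT);
  H5Awrite(att, type, value.empty() ? "" : value.c_str());
  H5Aclose(att); H5Sclose(sp); H5Tclose(type);
}

void write_double_attr(hid_t loc, const char* name, double value) {
  hid_t sp = H5Screate(H5S_SCALAR);
  hid_t att = H5Acreate2(loc, name, H5T_NATIVE_DOUBLE, sp, H5P_DEFAULT,
                         H5P_DEFAULT);
  H5Awrite(att, H5T_NATIVE_DOUBLE, &value);
  H5Aclose(att); H5Sclose(sp);
}

std::string read_string_attr(hid_t loc, const char* name, const char* fallback) {
  if (H5Aexists(loc, name) <= 0) return fallback;
  hid_t att = H5Aopen(loc, name, H5P_DEFAULT);
  hid_t type = H5Aget_type(att);
  size_t sz = H5Tget_size(type);
  std::string out;
  if (H5Tis_variable_str(type) > 0) {
    char* buf = nullptr;
    hid_t mtype = H5Tcopy(H5T_C_S1);
    H5Tset_size(mtype, H5T_VARIABLE);
    H5Aread(att, mtype, &buf);
    if (buf) { out = buf; free(buf); }
    H5Tclose(mtype);
  } else {
    std::vector<char> buf(sz + 1, '\0');
    H5Aread(att, type, buf.data());
    out = std::string(buf.data());
  }
  H5Tclose(type); H5Aclose(att);
  return out;
}

double read_double_attr(hid_t loc, const char* name, double fallback) {
  if (H5Aexists(loc, name) <= 0) return fallback;
  hid_t att = H5Aopen(loc, name, H5P_DEFAULT);
  double v = fallback;
  H5Aread(att, H5T_NATIVE_DOUBLE, &v);
  H5Aclose(att);
  return v;
}

} // namespace

// [[Rcpp::export(name = ".h5_write_stack")]]
void h5_write_stack(std::string path, List frames, Nullable<IntegerMatrix> mask,
                    CharacterVector frame_ids, double beam_center_row,
                    double beam_center_col, std::string source_tag,
                    std::string storage = "int32") {
  const int n = frames.size();
  if (n == 0) stop("frame stack must be non-empty");
  NumericMatrix f0 = frames[0];
  const hsize_t H = f0.nrow(), W = f0.ncol();
  const bool as_float = storage == "float32";
  if (!as_float && storage != "int32")
    stop("storage must be 'int32' or 'float32'");

  H5File file(H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT));
  if (file.id < 0) stop("cannot create HDF5 file '%s'", path.c_str());

  // frames: pack R column-major matrices into one C row-major buffer
  std::vector<int> ibuf;
  std::vector<float> fbuf;
  if (as_float) fbuf.resize(static_cast<size_t>(n) * H * W);
  else ibuf.resize(static_cast<size_t>(n) * H * W);
  for (int k = 0; k < n; ++k) {
    NumericMatrix fr = frames[k];
    if (static_cast<hsize_t>(fr.nrow()) != H ||
        static_cast<hsize_t>(fr.ncol()) != W)
      stop("all frames must share one shape");
    size_t base = static_cast<size_t>(k) * H * W;
    for (hsize_t i = 0; i < H; ++i)
      for (hsize_t j = 0; j < W; ++j) {
        if (as_float)
          fbuf[base + i * W + j] = static_cast<float>(fr(i, j));
        else
          ibuf[base + i * W + j] = static_cast<int>(std::lround(fr(i, j)));
      }
  }
  hsize_t fdims[3] = {static_cast<hsize_t>(n), H, W};
  hid_t fsp = H5Screate_simple(3, fdims, NULL);
  hid_t fds = H5Dcreate2(file.id, "/frames",
                         as_float ? H5T_IEEE_F32LE : H5T_STD_I32LE, fsp,
                         H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
  if (fds < 0) stop("cannot create /frames dataset");
  if (as_float)
    H5Dwrite(fds, H5T_NATIVE_FLOAT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
             fbuf.data());
  else
    H5Dwrite(fds, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
             ibuf.data());
  H5Dclose(fds); H5Sclose(fsp);

  if (mask.isNotNull()) {
    IntegerMatrix m(mask);
    if (static_cast<hsize_t>(m.nrow()) != H ||
        static_cast<hsize_t>(m.ncol()) != W)
      stop("mask shape must match frame shape");
    std::vector<unsigned char> mbuf(static_cast<size_t>(H) * W);
    for (hsize_t i = 0; i < H; ++i)
      for (hsize_t j = 0; j < W; ++j)
        mbuf[i * W + j] = m(i, j) ? 1 : 0;
    hsize_t mdims[2] = {H, W};
    hid_t msp = H5Screate_simple(2, mdims, NULL);
    hid_t mds = H5Dcreate2(file.id, "/mask", H5T_STD_U8LE, msp, H5P_DEFAULT,
                           H5P_DEFAULT, H5P_DEFAULT);
    H5Dwrite(mds, H5T_NATIVE_UCHAR, H5S_ALL, H5S_ALL, H5P_DEFAULT, mbuf.data());
    H5Dclose(mds); H5Sclose(msp);
  }

  // frame ids as variable-length strings
  {
    std::vector<std::string> ids(n);
    std::vector<const char*> cids(n);
    for (int k = 0; k < n; ++k) {
      ids[k] = as<std::string>(frame_ids[k]);
      cids[k] = ids[k].c_str();
    }
    hid_t stype = H5Tcopy(H5T_C_S1);
    H5Tset_size(stype, H5T_VARIABLE);
    H5Tset_cset(stype, H5T_CSET_UTF8);
    hsize_t idims[1] = {static_cast<hsize_t>(n)};
    hid_t isp = H5Screate_simple(1, idims, NULL);
    hid_t ids_ds = H5Dcreate2(file.id, "/frame_ids", stype, isp, H5P_DEFAULT,
                              H5P_DEFAULT, H5P_DEFAULT);
    H5Dwrite(ids_ds, stype, H5S_ALL, H5S_ALL, H5P_DEFAULT, cids.data());
    H5Dclose(ids_ds); H5Sclose(isp); H5Tclose(stype);
  }

  write_double_attr(file.id, "beam_center_row", beam_center_row);
  write_double_attr(file.id, "beam_center_col", beam_center_col);
  write_string_attr(file.id, "source_tag", source_tag);
}

// [[Rcpp::export(name = ".h5_read_stack")]]
List h5_read_stack(std::string path) {
  H5File file(H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT));
  if (file.id < 0) stop("cannot open HDF5 file '%s'", path.c_str());
  if (H5Lexists(file.id, "/frames", H5P_DEFAULT) <= 0)
    stop("format error: missing /frames dataset in '%s'", path.c_str());

  hid_t fds = H5Dopen2(file.id, "/frames", H5P_DEFAULT);
  hid_t fsp = H5Dget_space(fds);
  if (H5Sget_simple_extent_ndims(fsp) != 3) {
    H5Sclose(fsp); H5Dclose(fds);
    stop("format error: /frames must be a 3-d dataset");
  }
  hsize_t fdims[3];
  H5Sget_simple_extent_dims(fsp, fdims, NULL);
  const size_t n = fdims[0], H = fdims[1], W = fdims[2];
  hid_t dtype = H5Dget_type(fds);
  const bool is_int = H5Tget_class(dtype) == H5T_INTEGER;
  H5Tclose(dtype);

  List frames(n);
  if (is_int) {
    std::vector<int> buf(n * H * W);
    H5Dread(fds, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
    for (size_t k = 0; k < n; ++k) {
      IntegerMatrix fr(H, W);
      size_t base = k * H * W;
      for (size_t i = 0; i < H; ++i)
        for (size_t j = 0; j < W; ++j)
          fr(i, j) = buf[base + i * W + j];
      frames[k] = fr;
    }
  } else {
    std::vector<double> buf(n * H * W);
    H5Dread(fds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
            buf.data());
    for (size_t k = 0; k < n; ++k) {
      NumericMatrix fr(H, W);
      size_t base = k * H * W;
      for (size_t i = 0; i < H; ++i)
        for (size_t j = 0; j < W; ++j)
          fr(i, j) = buf[base + i * W + j];
      frames[k] = fr;
    }
  }
  H5Sclose(fsp); H5Dclose(fds);

  SEXP mask_out = R_NilValue;
  if (H5Lexists(file.id, "/mask", H5P_DEFAULT) > 0) {
    hid_t mds = H5Dopen2(file.id, "/mask", H5P_DEFAULT);
    hid_t msp = H5Dget_space(mds);
    hsize_t mdims[2] = {0, 0};
    int nd = H5Sget_simple_extent_ndims(msp);
    if (nd == 2) H5Sget_simple_extent_dims(msp, mdims, NULL);
    if (nd != 2 || mdims[0] != H || mdims[1] != W) {
      H5Sclose(msp); H5Dclose(mds);
      stop("format error: /mask shape does not match frame shape");
    }
    std::vector<unsigned char> mbuf(H * W);
    H5Dread(mds, H5T_NATIVE_UCHAR, H5S_ALL, H5S_ALL, H5P_DEFAULT, mbuf.data());
    H5Sclose(msp); H5Dclose(mds);
    IntegerMatrix m(H, W);
    for (size_t i = 0; i < H; ++i)
      for (size_t j = 0; j < W; ++j)
        m(i, j) = mbuf[i * W + j];
    mask_out = m;
  }

  CharacterVector ids(n);
  bool have_ids = false;
  if (H5Lexists(file.id, "/frame_ids", H5P_DEFAULT) > 0) {
    hid_t ids_ds = H5Dopen2(file.id, "/frame_ids", H5P_DEFAULT);
    hid_t isp = H5Dget_space(ids_ds);
    hsize_t idims[1] = {0};
    if (H5Sget_simple_extent_ndims(isp) == 1)
      H5Sget_simple_extent_dims(isp, idims, NULL);
    if (idims[0] == n) {
      hid_t stype = H5Tcopy(H5T_C_S1);
      H5Tset_size(stype, H5T_VARIABLE);
      H5Tset_cset(stype, H5T_CSET_UTF8);
      std::vector<char*> cids(n, nullptr);
      H5Dread(ids_ds, stype, H5S_ALL, H5S_ALL, H5P_DEFAULT, cids.data());
      for (size_t k = 0; k < n; ++k)
        ids[k] = cids[k] ? cids[k] : "";
      H5Dvlen_reclaim(stype, isp, H5P_DEFAULT, cids.data());
      H5Tclose(stype);
      have_ids = true;
    }
    H5Sclose(isp); H5Dclose(ids_ds);
  }
  if (!have_ids)
    for (size_t k = 0; k < n; ++k)
      ids[k] = "f" + std::to_string(k + 1);

  return List::create(
      _["frames"] = frames, _["mask"] = mask_out, _["frame_ids"] = ids,
      _["beam_center_row"] = read_double_attr(file.id, "beam_center_row",
                                              (H + 1) / 2.0),
      _["beam_center_col"] = read_double_attr(file.id, "beam_center_col",
                                              (W + 1) / 2.0),
      _["source_tag"] = read_string_attr(file.id, "source_tag", ""));
}
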