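# HDF5 headers/libs live in the same prefix as R itself (R_HOME = <prefix>/lib/R)
HDF5_PREFIX = $(R_HOME)/../..
PKG_CPPFLAGS = -I$(HDF5_PREFIX)/include
PKG_LIBS = -L$(HDF5_PREFIX)/lib -Wl,-rpath,$(HDF5_PREFIX)/lib -lhdf5
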