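design,band,method,width_nm,note
P10BP10,gap,TEM,24.9,dark band width
P10BP10,overlap,TEM,10.0,light band width (approximate)
P10BP10,period,cryoET-FFT,32.4,Fourier periodicity of tomogram slice
P10BP10,period,cryoET-realspace,33.2,real-space periodicity
P10BP10,period,AFM,32.7,Fourier periodicity of AFM profile
P10BBP10,period,cryoET-FFT,55.6,Fourier periodicity of tomogram slice
P10BBP10,gap,TEM,59.0,dark band width
R5BE5,overlap,TEM,5.8,light band mean width
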