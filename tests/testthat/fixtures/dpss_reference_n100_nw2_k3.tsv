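taper1	taper2	taper3
3.091441389749e-03	1.806444934864e-02	6.481755308626e-02
4.126692241187e-03	2.204034242207e-02	7.256780136311e-02
5.315076010932e-03	2.632501269518e-02	8.029299247003e-02
6.665148997699e-03	3.090528827476e-02	8.791823544029e-02
8.184853980029e-03	3.576439763568e-02	9.536707611240e-02
9.881415772570e-03	4.088198230486e-02	1.025623171164e-01
1.176123896502e-02	4.623414847086e-02	1.094268656979e-01
1.382980895620e-02	5.179355802886e-02	1.158845996807e-01
1.609159739316e-02	5.752955912679e-02	1.218612414894e-01
1.854997310978e-02	6.340835582558e-02	1.272852298910e-01
2.120711963222e-02	6.939321602915e-02	1.320885789853e-01
2.406396027841e-02	7.544471638475e-02	1.362077139678e-01
2.712009182677e-02	8.152102240606e-02	1.395842733192e-01
3.037372766553e-02	8.757820163578e-02	1.421658673331e-01
3.382165125909e-02	9.357056724749e-02	1.439067832828e-01
3.745918068173e-02	9.945104909232e-02	1.447686280420e-01
4.128014487385e-02	1.051715888308e-01	1.447208996082e-01
4.527687217096e-02	1.106835554576e-01	1.437414797259e-01
4.944019154339e-02	1.159381772338e-01	1.418170406575e-01
5.375944686527e-02	1.208869857854e-01	1.389433601018e-01
5.822252440664e-02	1.254822679233e-01	1.351255392888e-01
6.281589361305e-02	1.296775205774e-01	1.303781203850e-01
6.752466110533e-02	1.334279041293e-01	1.247251005081e-01
7.233263769846e-02	1.366906893735e-01	1.181998408554e-01
7.722241810468e-02	1.394256933325e-01	1.108448706890e-01
8.217547285432e-02	1.415956992064e-01	1.027115871714e-01
8.717225183799e-02	1.431668558393e-01	9.385985329840e-02
9.219229874930e-02	1.441090522512e-01	8.435749740619e-02
9.721437558792e-02	1.443962629913e-01	7.427971893495e-02
1.022165962709e-01	1.440068603355e-01	6.370840628214e-02
1.071765682967e-01	1.429238896581e-01	5.273137367206e-02
1.120715413124e-01	1.411353046676e-01	4.144152498233e-02
1.168785613518e-01	1.386341595866e-01	2.993595339416e-02
1.215746294401e-01	1.354187557940e-01	1.831498655713e-02
1.261368632040e-01	1.314927409073e-01	6.681187671078e-03
1.305426600782e-01	1.268651587769e-01	-4.861676522520e-03
1.347698606715e-01	1.215504493728e-01	-1.620968938692e-02
1.387969108357e-01	1.155683980733e-01	-2.725984789765e-02
1.426030209822e-01	1.089440344012e-01	-3.791112405116e-02
1.461683212006e-01	1.017074807894e-01	-4.806551217474e-02
1.494740107646e-01	9.389375249754e-02	-5.762905024309e-02
1.525025006518e-01	8.554251032408e-02	-6.651280355546e-02
1.552375477599e-01	7.669776827219e-02	-7.463379951773e-02
1.576643795749e-01	6.740755881451e-02	-8.191590280084e-02
1.597698081283e-01	5.772355886599e-02	-8.829062080511e-02
1.615423321769e-01	4.770068000227e-02	-9.369783014086e-02
1.629722266469e-01	3.739662685335e-02	-9.808641573081e-02
1.640516184994e-01	2.687142795161e-02	-1.014148151371e-01
1.647745483022e-01	1.618694361608e-02	-1.036514618045e-01
1.651370169269e-01	5.406355707934e-03	-1.047751220775e-01
1.651370169269e-01	-5.406355707928e-03	-1.047751220775e-01
1.647745483022e-01	-1.618694361607e-02	-1.036514618045e-01
1.640516184994e-01	-2.687142795161e-02	-1.014148151371e-01
1.629722266469e-01	-3.739662685335e-02	-9.808641573081e-02
1.615423321769e-01	-4.770068000227e-02	-9.369783014086e-02
1.597698081283e-01	-5.772355886598e-02	-8.829062080511e-02
1.576643795749e-01	-6.740755881450e-02	-8.191590280084e-02
1.552375477599e-01	-7.669776827218e-02	-7.463379951773e-02
1.525025006518e-01	-8.554251032408e-02	-6.651280355546e-02
1.494740107646e-01	-9.389375249753e-02	-5.762905024309e-02
1.461683212006e-01	-1.017074807894e-01	-4.806551217474e-02
1.426030209822e-01	-1.089440344012e-01	-3.791112405116e-02
1.387969108357e-01	-1.155683980733e-01	-2.725984789765e-02
1.347698606715e-01	-1.215504493728e-01	-1.620968938692e-02
1.305426600782e-01	-1.268651587769e-01	-4.861676522519e-03
1.261368632040e-01	-1.314927409073e-01	6.681187671079e-03
1.215746294401e-01	-1.354187557940e-01	1.831498655714e-02
1.168785613518e-01	-1.386341595866e-01	2.993595339416e-02
1.120715413124e-01	-1.411353046676e-01	4.144152498233e-02
1.071765682967e-01	-1.429238896581e-01	5.273137367206e-02
1.022165962709e-01	-1.440068603355e-01	6.370840628214e-02
9.721437558792e-02	-1.443962629913e-01	7.427971893495e-02
9.219229874930e-02	-1.441090522512e-01	8.435749740620e-02
8.717225183799e-02	-1.431668558393e-01	9.385985329840e-02
8.217547285432e-02	-1.415956992064e-01	1.027115871714e-01
7.722241810468e-02	-1.394256933325e-01	1.108448706890e-01
7.233263769846e-02	-1.366906893735e-01	1.181998408554e-01
6.752466110533e-02	-1.334279041293e-01	1.247251005081e-01
6.281589361305e-02	-1.296775205774e-01	1.303781203850e-01
5.822252440664e-02	-1.254822679233e-01	1.351255392888e-01
5.375944686527e-02	-1.208869857854e-01	1.389433601018e-01
4.944019154339e-02	-1.159381772338e-01	1.418170406575e-01
4.527687217096e-02	-1.106835554576e-01	1.437414797259e-01
4.128014487385e-02	-1.051715888308e-01	1.447208996082e-01
3.745918068173e-02	-9.945104909232e-02	1.447686280420e-01
3.382165125909e-02	-9.357056724749e-02	1.439067832828e-01
3.037372766553e-02	-8.757820163578e-02	1.421658673331e-01
2.712009182677e-02	-8.152102240606e-02	1.395842733192e-01
2.406396027841e-02	-7.544471638475e-02	1.362077139678e-01
2.120711963222e-02	-6.939321602915e-02	1.320885789853e-01
1.854997310978e-02	-6.340835582558e-02	1.272852298910e-01
1.609159739316e-02	-5.752955912679e-02	1.218612414894e-01
1.382980895620e-02	-5.179355802886e-02	1.158845996807e-01
1.176123896502e-02	-4.623414847086e-02	1.094268656979e-01
9.881415772570e-03	-4.088198230486e-02	1.025623171164e-01
8.184853980029e-03	-3.576439763568e-02	9.536707611240e-02
6.665148997699e-03	-3.090528827476e-02	8.791823544029e-02
5.315076010932e-03	-2.632501269518e-02	8.029299247003e-02
4.126692241187e-03	-2.204034242207e-02	7.256780136311e-02
3.091441389749e-03	-1.806444934864e-02	6.481755308626e-02
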