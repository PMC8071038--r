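subject_id,group,age,sex,handedness
case_0001,case,26.592667829458669,M,R
case_0002,case,18.504054487021634,M,R
case_0003,case,13.771477312216254,M,R
case_0004,case,24.154341980066075,M,R
case_0005,case,21.992952068145531,M,R
case_0006,case,19.205715245506006,M,R
case_0007,case,15.618660610304266,M,R
case_0008,case,22.934184672374577,M,R
control_0001,control,21.23630158874311,M,R
control_0002,control,12.898533500000404,M,R
control_0003,control,19.092266801507122,M,R
control_0004,control,41.680047097105557,M,R
control_0005,control,15.187277632698605,M,R
control_0006,control,13.964214073646914,M,R
control_0007,control,19.103095061469368,M,R
control_0008,control,24.729801673235841,M,R
control_0009,control,11.796053793623871,M,R
control_0010,control,27.191352496366196,M,R
control_0011,control,16.405555006327877,M,R
control_0012,control,15.979471104094145,M,R
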