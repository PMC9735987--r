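image_id,dataset,raw_diagnosis
26_training,DRIVE,Background diabetic retinopathy
25_training,DRIVE,Background diabetic retinopathy
32_training,DRIVE,Background diabetic retinopathy
14_test,DRIVE,Background diabetic retinopathy
08_test,DRIVE,Background diabetic retinopathy
03_test,DRIVE,Background diabetic retinopathy
17_test,DRIVE,Background diabetic retinopathy
im0001,STARE,Background diabetic retinopathy
im0002,STARE,Arteriosclerotic retinopathy and choroidal neovascularization
im0004,STARE,Cilio-retinal artery occlusion or arteriosclerotic retinopathy
im0005,STARE,Central retinal artery occlusion and central retinal vein occlusion
im0139,STARE,Background diabetic retinopathy
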