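metabolite,class,experiment,genotype,replicate,value
maltose,carbohydrate,1,SH,1,1119.8
maltose,carbohydrate,1,YK,1,678.6
maltose,carbohydrate,2,SH,1,1081.4
maltose,carbohydrate,2,YK,1,846.2
glucose,carbohydrate,1,SH,1,41843.5
glucose,carbohydrate,1,YK,1,28552.0
glucose,carbohydrate,2,SH,1,16547.4
glucose,carbohydrate,2,YK,1,6251.4
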