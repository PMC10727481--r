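window,class,size,precision_pct,recall_pct,final_model
5,upward_linear,3,50,67,cosine_knn
5,s_shape,4,67,50,cosine_knn
6,upward_linear,3,75,100,linear_svm
6,s_shape,4,100,75,linear_svm
7,upward_linear,3,100,100,cosine_knn
7,s_shape,4,100,100,cosine_knn
8,upward_linear,3,60,100,cosine_knn
8,s_shape,4,100,50,cosine_knn
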