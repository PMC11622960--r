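class_name,n_images
Apple with scab,630
Apple with black rot,621
Apple with cedar apple rust,275
Healthy apple,1645
Blueberry with healthy,1502
Cherry with healthy,854
Cherry with powdery mildew,1052
Corn with grey leaf spot,513
Corn with common rust,1192
Healthy corn,1162
Corn with northern leaf blight,985
Grape with black rot,1180
Grape with black measles,1383
Healthy grape,423
Grape with leaf blight,1076
Orange with Huanglongbing,5507
Peach with bacterial spot,2297
Healthy peach,360
Pepper with bacterial spot,997
Healthy pepper,1478
Potato with early blight,1000
Healthy potato,152
Potato with late blight,1000
Healthy raspberry,371
Healthy soybean,5090
Squash with powdery mildew,1835
Healthy strawberry,456
Strawberry with leaf scorch,1109
Tomato with bacterial spot,2127
Tomato with early blight,1001
Healthy tomato,1591
Tomato with leaf mold,952
Tomato with septoria leaf spot,1771
Tomato with two spotted spider mite,1676
Tomato with target spot,1404
Tomato with mosaic virus,373
Tomato with yellow leaf curl virus,5357
Tomato with late blight,1909
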